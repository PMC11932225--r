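---
title: "Methods: simulating and analysing bimanual finger-tapping screening data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing bimanual finger-tapping screening data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimotap)
```

## The measurement and the nine parameters

bimotap analyses bimanual thumb–index finger tapping recorded as two
aperture-distance waveforms (mm versus time), one per hand, as produced
by magnetic-sensor tapping devices such as the UB-2. A participant taps
for 15 s per task with a 40 mm target aperture, once with both hands
moving together (in-phase) and once with the hands alternating by half a
cycle (anti-phase, the harder, asymmetric condition). From each trial
the package computes the nine standard coordination parameters:

* per hand — total traveling distance; mean, SD and time-slope of the
  per-cycle local-maximum aperture (the slope reflects amplitude decay
  under fatigue and is 0 in its absence); number of taps; mean, SD and
  inverse-mean (frequency) of the inter-tap interval;
* per trial — the SD of the inter-hand phase difference, with one tap
  cycle mapped to 360°.

Larger travel distance, amplitude, tap count and frequency indicate
better coordination; all the variability measures, the interval mean and
a more negative fatigue slope indicate worse coordination.

## Tap detection

The device's own event detector is not public, so the package declares
its convention rather than inferring one: peaks are local maxima with
topographic prominence of at least 4 mm (10% of the target aperture;
plateaus resolve to their first sample), and a tap event is the minimum
sample between each consecutive pair of prominent peaks. Contacts at the
very edges of the recording that are not flanked by peaks on both sides
are therefore not events. On a 15 s trial with ~55 cycles this
convention counts one to two fewer events than the number of physical
closures; all downstream comparisons are unaffected because every trial
is treated identically.

Two sub-sample refinements remove sampling-grid quantisation (10 ms at
the default 100 Hz) from the timing parameters:

* peak coordinates come from a local least-squares quadratic vertex;
* contact coordinates come from a two-sided junction fit,
  `y = y0 + a (t − t0)² [t < t0] + b (t − t0)² [t ≥ t0]`, with the vertex
  profiled over a sub-sample grid. A single symmetric parabola is biased
  toward the flatter of the two adjoining movement arches — adjacent
  cycles differ in duration and amplitude exactly when the inter-hand lag
  is large — and that bias shrinks phase deviations by several percent.
  The two-sided fit removes it.

Refinement can be disabled (`refine = FALSE`) to reproduce raw
sample-grid behaviour.

## Phase difference

With the right hand as reference (the analysed population is
right-handed; left-handers are excluded), each right-hand cycle
`c_k = r_{k+1} − r_k` spans 360°. The left contact nearest the task
target (the right contact for in-phase, the cycle midpoint for
anti-phase) yields the lag angle `360 (t_left − r_k)/c_k`, wrapped to
(−180°, 180°] around the target. The reported parameter is the circular
standard deviation `sqrt(−log ρ²)` with the small-sample correction
`ρ̂² = (n R̄² − 1)/(n − 1)`, which is exactly unbiased for `ρ²` under
i.i.d. directions; without it the 20–60 cycles of a 15 s trial
underestimate the spread by 1–3%. A 15 s trial is short enough that the
wrapped-normal and linear views of these angles coincide to well below
measurement error at the spreads seen in practice (25–45°).

## The synthetic-data generator

No raw recordings are distributed with studies of this design, so the
package ships a generator whose defaults encode the published cohort
structure: group sizes 97/102/222 (young 18–22, young-old 65–74, old-old
≥75), the published sex counts and age means/SDs, and one parameter cell
per (group, task, hand) holding the interval mean/SD, amplitude mean/SD
and fatigue slope, plus a phase-jitter SD per (group, task).

A trial is generated as follows:

1. Right-hand contacts start at t = 0 with gaps drawn from a normal
   distribution truncated below at 0.05 s (means 0.27–0.59 s, so the
   truncation is inert in practice; the published tables give only
   means and SDs, and a truncated normal is the least-structured
   nonnegative choice).
2. Each left contact is its paired right contact plus
   `Normal(0, σ)` (in-phase) or `Normal(c_k/2, σ)` (anti-phase), with
   `σ = phase_sd/360 × c_k`. Phase locking means both hands share the
   right-hand rhythm: the small published left/right differences in
   interval means (e.g. 0.28 vs 0.27 s) cannot be produced by any
   phase-locked generator, and the left-hand timing target is therefore
   the right-hand cell. The published left-worse-than-right asymmetry is
   carried by the variability parameters instead: the coupling itself
   inflates the left hand's inter-tap-interval SD, and the per-hand
   amplitude cells give the left hand a larger local-maximum SD.
3. Every open–close cycle is a raised-cosine arch from 0 mm at contact to
   a peak drawn from
   `Normal(amplitude_mean + fatigue_slope × (t − duration/2), amplitude_sd)`,
   floored at 1 mm. Centring the linear fatigue drift mid-trial makes the
   trial-average amplitude equal the cell's amplitude mean, which is what
   the published cell statistics describe.
4. The waveform is sampled at 100 Hz (the sampling rate of the source
   device is unpublished; 100 Hz resolves 2–4 Hz tapping comfortably and
   is configurable) and Gaussian sensor noise of SD 0.2 mm — small
   against the 40 mm aperture — is added and clipped at 0.
5. The final truncated cycle is rendered only when at least three
   quarters of it fit the window; the rendered trailing peak has then
   always descended by half its amplitude before the recording ends, so
   whether the last contact is detectable is a deterministic property of
   the generated contact times. Each trial carries its generating contact
   and peak times as a `truth` attribute, giving every downstream test an
   exact oracle.

Between-subject heterogeneity multiplies each subject's interval and
amplitude means by `Normal(1, 0.15)` factors (truncated at 0.5, shared
across that subject's hands and tasks). The published cell SDs mix
between- and within-subject dispersion without reporting the split, so
the 0.15 coefficient of variation is a package choice: it reproduces
cell SDs of roughly the published order while leaving the within-trial
SDs at their published values.

What the generator does **not** emulate: biomechanics (velocity
profiles, muscle dynamics), sequential-dependence structure in tap
intervals (gaps are exchangeable), asymmetric or skewed interval
distributions, sensor drift and artefacts, or the (unpublished)
processing inside the device. Passing parameter-recovery tests therefore
demonstrates that the analysis chain is correct and well calibrated
under the published summary structure — not that it would be unbiased
under every real-data pathology.

## Cohort screening rules

The exclusion rules are applied in a fixed order so the log is
deterministic (the source protocol lists criteria without an
application order): pre-screened disorder flag, left-handedness, maximum
aperture ≥ 300 mm on any trial (a sensor-range artefact), incomplete
trials, age outside the recruited bands (18–22, 65–74, ≥75; intermediate
ages were never recruited and are logged as `age_out_of_range`), and —
for the older groups only — MMSE ≤ 23. The 300 mm rule is evaluated over
both channels of every trial, the most conservative reading.

## Group statistics

The distance and interval parameters are analysed with a three-way
mixed-design ANOVA (between: group; within: hand, task), the phase
parameter with the two-way variant (within: task). Tests use Type III
sums of squares with sum-to-zero contrasts via the multivariate
linear-model route (`car::Anova` with an intra-subject design), matching
the SPSS GLM convention the field reports; both within factors have two
levels, so sphericity corrections are moot. Post-hoc contrasts are
pairwise t tests (independent for group, paired for within factors),
Bonferroni-adjusted with the family being the contrasts within one slice
(three group contrasts per task slice, for example); for two-way
interactions the simple effects of each factor within the other's levels
are tested. The post-hoc gate refuses non-significant effects unless
`force = TRUE` (used for calibration studies). Analyses are
complete-case; α = 0.05 throughout.

## ROC age cutoffs

The screening question is: at what age does low bimanual-coordination
performance become detectable? The published analysis does not define
the binary state variable behind its ROC table, so the package makes the
rule explicit and configurable: by default, low performance is a
whole-sample median split in the parameter's worse direction (ties to
the better class); an alternative marks values more than 1 SD worse than
the young-adult mean (`young_ref_1sd`). The rule used is recorded in the
output. Because the state definition is a package choice, numerical
equality with the published AUC/cutoff values is not claimed — the
package validates the arithmetic identities of the published table
(Youden index = Sn + Sp − 1 in all 12 rows; 95% CI = AUC ± 1.96 SE) and
the procedure's structure.

Age is the predictor, positive = low performance. The AUC is the
Mann–Whitney pairwise concordance with ties at one half, its SE is the
Hanley–McNeil closed form (the nonparametric default of the statistical
software the field uses), and the cutoff maximises the Youden index over
thresholds at midpoints between adjacent distinct ages — with integer
ages the only convention that can produce the familiar half-year
cutoffs — with ties broken toward the lower threshold. The panel is
restricted to parameters whose post-hoc contrasts separate all three age
groups in both tasks (tap count, interval mean, frequency under the
default profiles).

## Numerical and design choices

* Sample (n − 1) standard deviations everywhere.
* Undefined features (too few taps) propagate as `NA`, never as zeros.
* Degenerate inputs are errors with messages (empty classes in ROC,
  missing within-cells in ANOVA listing the offending subjects, zero
  margins in the chi-square) rather than silent results.
* All randomness flows from explicit integer seeds; a single master seed
  fans out to per-stage seeds through a fixed 31-bit derivation, so every
  pipeline stage is independently reproducible and full reruns are
  byte-identical.
* Problem sizes in the test-suite simulation studies are chosen to hold
  Monte-Carlo error well below the effects under test: 200 trials per
  recovery cell, a 120-participant cohort for ordering and correlation
  patterns, 500 replicates for the type-I-error audit (the audit
  generates parameter values directly from a shared null distribution —
  group labels carry no information — since the property under test
  belongs to the ANOVA machinery, not the waveform layer), 500 random
  trials for oracle equivalence and 1000 instances for the ROC
  enumeration checks.

## Known limitations

* Phase locking ties both hands to one rhythm; per-hand interval means
  cannot differ systematically (see above).
* The flanked-minimum tap convention undercounts physical closures by
  1–2 per trial relative to a device that counts every contact.
* The state variable behind the ROC stage is a package definition;
  cutoffs and AUCs shift with the rule chosen, and only the orderings
  and identities are asserted.
* With real recordings (`read_trial`/ingest mode) the detector assumes
  reasonably clean aperture waveforms; no artefact rejection or
  filtering beyond prominence-based detection is applied.
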