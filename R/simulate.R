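#' Default simulation profiles for the three age groups
#'
#' Returns the generator parameterisation used throughout the package: one
#' cell per (group, task, hand) holding the within-trial tapping-interval
#' mean/SD (s), local-maximum amplitude mean/SD (mm) and fatigue slope
#' (mm/s), plus one inter-hand phase-jitter SD (degrees) per (group, task).
#' The numbers are the published UB-2 cohort cell statistics for young
#' adults (YA), young-old adults (YOA) and old-old adults (OOA) performing
#' the in-phase and anti-phase tasks, so cohorts simulated from these
#' defaults carry the group/task/hand structure the downstream statistics
#' assume.
#'
#' @param cv_between Coefficient of variation of the per-subject scaling
#'   applied to interval and amplitude means (between-subject
#'   heterogeneity); default 0.15.
#' @return An object of class `group_profiles`.
#' @examples
#' p <- default_profiles()
#' profile_cell(p, "YA", "in_phase", "left")$interval_mean
#' @export
default_profiles <- function(cv_between = 0.15) {
  g <- rep(GROUPS, times = 4)
  cells <- tibble::tibble(
    group = g,
    task  = rep(TASKS, each = 6),
    hand  = rep(rep(HANDS, each = 3), times = 2),
    # order within each block: YA, YOA, OOA
    interval_mean = c(0.28, 0.34, 0.38,   0.27, 0.34, 0.38,
                      0.37, 0.51, 0.59,   0.37, 0.50, 0.59),
    interval_sd   = c(0.03, 0.04, 0.04,   0.02, 0.03, 0.04,
                      0.04, 0.08, 0.10,   0.03, 0.06, 0.08),
    amplitude_mean = c(41.07, 46.81, 48.11,   40.25, 47.01, 48.78,
                       49.50, 60.55, 62.22,   47.39, 59.90, 63.15),
    amplitude_sd   = c(6.95, 6.71, 6.63,   5.26, 5.55, 5.70,
                       7.06, 7.36, 7.90,   5.45, 6.87, 7.09),
    fatigue_slope  = c(-0.14, -0.14, -0.09,   -0.08, 0.11, 0.03,
                       -0.21, -0.15, -0.15,   -0.11, -0.10, -0.17)
  )
  phase <- tibble::tibble(
    group = rep(GROUPS, 2),
    task  = rep(TASKS, each = 3),
    phase_sd = c(29.60, 27.27, 29.03, 25.88, 33.21, 40.57)
  )
  structure(list(cells = cells, phase = phase, cv_between = cv_between),
            class = "group_profiles")
}

#' @rdname default_profiles
#' @param profiles A `group_profiles` object.
#' @param group,task,hand Cell coordinates.
#' @export
profile_cell <- function(profiles, group, task, hand) {
  row <- profiles$cells[profiles$cells$group == group &
                        profiles$cells$task == task &
                        profiles$cells$hand == hand, ]
  if (nrow(row) != 1) {
    stop(sprintf("no profile for (%s, %s, %s)", group, task, hand),
         call. = FALSE)
  }
  as.list(row)
}

#' @rdname default_profiles
#' @export
profile_phase_sd <- function(profiles, group, task) {
  row <- profiles$phase[profiles$phase$group == group &
                        profiles$phase$task == task, ]
  if (nrow(row) != 1) {
    stop(sprintf("no phase profile for (%s, %s)", group, task), call. = FALSE)
  }
  row$phase_sd
}

#' @export
print.group_profiles <- function(x, ...) {
  cat("<group_profiles>", nrow(x$cells), "cells;",
      "between-subject CV", x$cv_between, "\n")
  print(x$cells, n = 4)
  invisible(x)
}

# Truncated-normal draws via rejection; lower bound only.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(pmax(mean, lower), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
  }
  out
}

#' Simulate thumb-index contact times for one hand
#'
#' The first contact occurs at t = 0; successive gaps are drawn
#' independently from a normal distribution truncated below at 0.05 s
#' (no physically meaningful tap cycle is shorter). Generation stops at
#' the last contact not exceeding `duration`.
#'
#' @param interval_mean Mean tapping interval in seconds (> 0).
#' @param interval_sd Within-trial SD of the interval in seconds (>= 0).
#' @param duration Trial duration in seconds.
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return Numeric vector of strictly increasing contact times starting at 0.
#' @examples
#' simulate_tap_times(0.25, 0, 15)  # 61 equally spaced contacts
#' @export
simulate_tap_times <- function(interval_mean, interval_sd, duration,
                               seed = NULL) {
  ct <- simulate_tap_times_impl(interval_mean, interval_sd, duration, seed)
  ct$contacts
}

# Internal variant keeping one contact beyond the window (used to render
# the final, truncated movement cycle).
simulate_tap_times_impl <- function(interval_mean, interval_sd, duration,
                                    seed = NULL) {
  if (!is.numeric(interval_mean) || interval_mean <= 0) {
    stop("interval_mean must be > 0", call. = FALSE)
  }
  if (!is.numeric(interval_sd) || interval_sd < 0) {
    stop("interval_sd must be >= 0", call. = FALSE)
  }
  run <- function() {
    n_guess <- ceiling(duration / max(interval_mean, 0.05)) + 10
    times <- 0
    repeat {
      gaps <- rtruncnorm_lower(n_guess, interval_mean, interval_sd, 0.05)
      times <- c(times, times[length(times)] + cumsum(gaps))
      if (times[length(times)] > duration) break
    }
    inside <- times <= duration + 1e-9
    list(contacts = times[inside], overshoot = times[which(!inside)[1]])
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# Raised-cosine arch rendering: for sample times t within [t0, t1) the
# aperture is peak/2 * (1 - cos(2*pi*(t - t0)/(t1 - t0))).
render_channel <- function(time, contacts, peaks) {
  d <- numeric(length(time))
  if (length(contacts) < 2) return(d)
  idx <- findInterval(time, contacts)
  live <- idx >= 1 & idx < length(contacts)
  k <- idx[live]
  u <- (time[live] - contacts[k]) / (contacts[k + 1] - contacts[k])
  d[live] <- peaks[k] / 2 * (1 - cos(2 * pi * u))
  d
}

#' Simulate one bimanual tapping trial
#'
#' Renders a two-channel thumb-index distance waveform. Right-hand contact
#' times come from [simulate_tap_times()]; each left-hand contact is the
#' paired right-hand contact plus a phase offset: Normal(0, sigma) for the
#' in-phase task and Normal(half the local right-hand cycle, sigma) for the
#' anti-phase task, with sigma = phase_sd/360 x local cycle duration. Every
#' open-close cycle is a raised-cosine arch from 0 mm (contact) up to a
#' peak drawn from Normal(amplitude_mean + fatigue_slope x (t - duration/2),
#' amplitude_sd), floored at 1 mm, so that the trial-average amplitude
#' matches the profile's amplitude mean despite the fatigue drift. The
#' final partial cycle is rendered only when its apex is resolvable inside
#' the recording window; additive sensor noise Normal(0, `noise_sd`) is
#' clipped at 0 mm.
#'
#' The returned trial carries a `truth` attribute with the generating
#' contact times, arch peak times/values and per-cycle phase offsets, used
#' as an independent oracle for the feature-extraction code.
#'
#' @param profiles A [default_profiles()]-style object.
#' @param participant List or one-row data frame with at least `id` and
#'   `group`; optional `interval_scale` / `amplitude_scale` personal
#'   multipliers (between-subject heterogeneity, default 1).
#' @param task `"in_phase"` or `"anti_phase"`.
#' @param seed Optional integer seed.
#' @param sampling_rate Sampling rate in Hz (default 100).
#' @param duration Trial length in seconds (default 15).
#' @param noise_sd Measurement noise SD in mm (default 0.2).
#' @return A [tapping_trial()] with a `truth` attribute.
#' @export
simulate_trial <- function(profiles, participant, task, seed = NULL,
                           sampling_rate = 100, duration = 15,
                           noise_sd = 0.2) {
  task <- match.arg(task, TASKS)
  participant <- as.list(participant)
  if (is.null(participant$group) || !(participant$group %in% GROUPS)) {
    stop("participant must carry a group (YA/YOA/OOA)", call. = FALSE)
  }
  i_scale <- if (is.null(participant$interval_scale)) 1 else participant$interval_scale
  a_scale <- if (is.null(participant$amplitude_scale)) 1 else participant$amplitude_scale
  prof_r <- profile_cell(profiles, participant$group, task, "right")
  prof_l <- profile_cell(profiles, participant$group, task, "left")
  psd <- profile_phase_sd(profiles, participant$group, task)

  build <- function() {
    rt <- simulate_tap_times_impl(prof_r$interval_mean * i_scale,
                                  prof_r$interval_sd, duration)
    r_all <- c(rt$contacts, rt$overshoot)
    n_r <- length(rt$contacts)

    # Per-contact phase offsets relative to the right hand; the local cycle
    # is the one starting at the paired right contact (last one reuses the
    # preceding cycle length).
    cyc <- diff(r_all)
    cyc_at <- c(cyc, cyc[length(cyc)])[seq_len(n_r + 1)]
    target <- if (task == "in_phase") 0 else cyc_at / 2
    delta <- stats::rnorm(n_r + 1, target, psd / 360 * cyc_at)
    l_all <- r_all + delta
    l_all[1] <- max(l_all[1], 0)
    l_all <- sort(l_all)
    # guarantee strict increase (phase jitter can in principle collide)
    l_all <- l_all + cumsum(c(0, diff(l_all) <= 0)) * 1e-6
    l_contacts <- l_all[l_all <= duration + 1e-9]
    if (length(l_contacts) == length(l_all)) l_all <- c(l_all, duration + cyc_at[length(cyc_at)])

    draw_peaks <- function(contacts_ext, prof) {
      mid <- (utils::head(contacts_ext, -1) + utils::tail(contacts_ext, -1)) / 2
      pmax(stats::rnorm(length(mid),
                        prof$amplitude_mean * a_scale +
                          prof$fatigue_slope * (mid - duration / 2),
                        prof$amplitude_sd), 1)
    }

    dt <- 1 / sampling_rate
    finish_hand <- function(all_contacts, n_inside, prof) {
      contacts_ext <- all_contacts[seq_len(n_inside + 1)]
      peaks <- draw_peaks(contacts_ext, prof)
      peak_t <- (utils::head(contacts_ext, -1) + utils::tail(contacts_ext, -1)) / 2
      # drop the trailing truncated cycle unless at least three quarters of
      # it fit the window: then the rendered apex has descended by half its
      # amplitude before the recording ends and is always resolvable,
      # keeping the generator's ground-truth peak list exact
      tcyc <- diff(utils::tail(contacts_ext, 2))
      if (peak_t[length(peak_t)] + tcyc / 4 > duration) {
        contacts_ext <- contacts_ext[-length(contacts_ext)]
        peaks <- peaks[-length(peaks)]
        peak_t <- peak_t[-length(peak_t)]
      }
      list(render_contacts = contacts_ext, peaks = peaks, peak_t = peak_t)
    }

    r_hand <- finish_hand(r_all, n_r, prof_r)
    l_hand <- finish_hand(l_all, length(l_contacts), prof_l)

    time <- seq(0, duration, by = dt)
    left <- render_channel(time, l_hand$render_contacts, l_hand$peaks)
    right <- render_channel(time, r_hand$render_contacts, r_hand$peaks)
    if (noise_sd > 0) {
      left <- pmax(left + stats::rnorm(length(time), 0, noise_sd), 0)
      right <- pmax(right + stats::rnorm(length(time), 0, noise_sd), 0)
    }
    trial <- tapping_trial(participant$id, task, sampling_rate,
                           left = left, right = right, duration = duration)
    attr(trial, "truth") <- list(
      left = list(contacts = l_contacts, peak_t = l_hand$peak_t,
                  peak_v = l_hand$peaks),
      right = list(contacts = rt$contacts, peak_t = r_hand$peak_t,
                   peak_v = r_hand$peaks),
      phase_sd = psd
    )
    trial
  }
  if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
}

# Contacts flanked by an in-window rendered peak on both sides: the count
# the waveform-based detector should reproduce.
truth_flanked_count <- function(truth_hand) {
  ct <- truth_hand$contacts
  pt <- truth_hand$peak_t
  if (!length(ct) || !length(pt)) return(0L)
  sum(vapply(ct, function(t0) any(pt < t0) && any(pt > t0), logical(1)))
}

#' Cohort specification for the simulator
#'
#' Defaults mirror the published screened cohort: 97 young adults
#' (25 male / 72 female, age 20.73 +/- 1.43), 102 young-old adults
#' (17 / 85, 70.77 +/- 2.70) and 222 old-old adults (52 / 170,
#' 80.71 +/- 4.38), ages resampled into each group's legal band.
#'
#' @param n Named integer vector of group sizes.
#' @param age_mean,age_sd Named numeric vectors per group.
#' @param males Named integer vector of male counts per group.
#' @param seed Integer seed driving the whole cohort.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = c(YA = 97, YOA = 102, OOA = 222),
                        age_mean = c(YA = 20.73, YOA = 70.77, OOA = 80.71),
                        age_sd = c(YA = 1.43, YOA = 2.70, OOA = 4.38),
                        males = c(YA = 25, YOA = 17, OOA = 52),
                        seed = 1L) {
  stopifnot(all(n > 0), all(males >= 0), all(males <= n))
  structure(list(n = n, age_mean = age_mean, age_sd = age_sd,
                 males = males, seed = as.integer(seed)),
            class = "cohort_spec")
}

age_range_for <- function(group) {
  switch(group, YA = c(18, 22), YOA = c(65, 74), OOA = c(75, 105))
}

#' Simulate a full cohort of participants and trials
#'
#' Draws participants per group (integer ages resampled into the group
#' band, sexes in the specified counts, per-subject interval/amplitude
#' scaling factors shared across that subject's tasks and hands) and
#' simulates one in-phase and one anti-phase trial per participant.
#' Fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param profiles A [default_profiles()]-style object.
#' @param sampling_rate,duration,noise_sd Passed to [simulate_trial()].
#' @return A [cohort()].
#' @export
simulate_cohort <- function(spec = cohort_spec(), profiles = default_profiles(),
                            sampling_rate = 100, duration = 15,
                            noise_sd = 0.2) {
  stopifnot(inherits(spec, "cohort_spec"))
  cv <- profiles$cv_between
  parts <- withr::with_seed(derive_seed(spec$seed, 1), {
    dplyr::bind_rows(lapply(GROUPS, function(g) {
      n <- spec$n[[g]]
      rng <- age_range_for(g)
      ages <- integer(0)
      while (length(ages) < n) {
        cand <- round(stats::rnorm(n, spec$age_mean[[g]], spec$age_sd[[g]]))
        ages <- c(ages, cand[cand >= rng[1] & cand <= rng[2]])
      }
      ages <- ages[seq_len(n)]
      sex <- sample(c(rep("male", spec$males[[g]]),
                      rep("female", n - spec$males[[g]])))
      tibble::tibble(
        id = sprintf("%s%03d", g, seq_len(n)),
        age = as.integer(ages),
        sex = sex,
        handedness = "right",
        mmse = if (g == "YA") NA_integer_ else
          as.integer(sample(24:30, n, replace = TRUE,
                            prob = c(1, 1, 2, 3, 4, 5, 6))),
        group = g,
        interval_scale = rtruncnorm_lower(n, 1, cv, 0.5),
        amplitude_scale = rtruncnorm_lower(n, 1, cv, 0.5)
      )
    }))
  })
  trials <- vector("list", 2 * nrow(parts))
  for (i in seq_len(nrow(parts))) {
    for (j in seq_along(TASKS)) {
      trials[[2 * (i - 1) + j]] <- simulate_trial(
        profiles, parts[i, ], TASKS[j],
        seed = derive_seed(spec$seed, 100 + 2 * i + j),
        sampling_rate = sampling_rate, duration = duration,
        noise_sd = noise_sd
      )
    }
  }
  cohort(parts, trials)
}
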