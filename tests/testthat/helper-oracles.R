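# Independent brute-force oracles (naive loops, no shared code with the
# package internals) plus small fixture builders.

oracle_total_distance <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + abs(x[i] - x[i - 1])
  s
}

oracle_interval_stats <- function(contact_times) {
  n <- length(contact_times)
  gaps <- c()
  for (i in 2:n) gaps <- c(gaps, contact_times[i] - contact_times[i - 1])
  m <- sum(gaps) / length(gaps)
  v <- sum((gaps - m)^2) / (length(gaps) - 1)
  list(number = n, ave = m, freq = 1 / m, sd = sqrt(v))
}

oracle_peak_stats <- function(peak_t, peak_v) {
  n <- length(peak_v)
  m <- sum(peak_v) / n
  v <- sum((peak_v - m)^2) / (n - 1)
  mt <- sum(peak_t) / n
  slope <- sum((peak_t - mt) * (peak_v - m)) / sum((peak_t - mt)^2)
  list(ave = m, sd = sqrt(v), slope = slope)
}

oracle_phase_sd <- function(left_t, right_t, task) {
  devs <- c()
  target <- if (task == "in_phase") 0 else 180
  for (k in 1:(length(right_t) - 1)) {
    ck <- right_t[k + 1] - right_t[k]
    tgt <- right_t[k] + if (task == "in_phase") 0 else ck / 2
    cand <- left_t[left_t >= right_t[k] - ck & left_t <= right_t[k + 1] + ck]
    if (length(cand) == 0) next
    tl <- cand[order(abs(cand - tgt))][1]
    ang <- 360 * (tl - right_t[k]) / ck - target
    while (ang > 180) ang <- ang - 360
    while (ang <= -180) ang <- ang + 360
    devs <- c(devs, ang)
  }
  if (length(devs) == 0) return(NA_real_)
  n <- length(devs)
  rad <- devs * pi / 180
  R2 <- (sum(cos(rad)) / n)^2 + (sum(sin(rad)) / n)^2
  rho2 <- max((n * R2 - 1) / (n - 1), 0)
  if (rho2 <= 0) return(Inf)
  if (rho2 >= 1) return(0)
  sqrt(-log(rho2)) * 180 / pi
}

oracle_auc <- function(predictor, states) {
  pos <- predictor[states == 1]
  neg <- predictor[states == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

oracle_youden <- function(predictor, states) {
  v <- sort(unique(predictor))
  thr <- (head(v, -1) + tail(v, -1)) / 2
  best <- -Inf; best_th <- NA
  for (th in thr) {
    sn <- mean(predictor[states == 1] >= th)
    sp <- mean(predictor[states == 0] < th)
    if (sn + sp - 1 > best + 1e-12) { best <- sn + sp - 1; best_th <- th }
  }
  list(cutoff = best_th, yi = best)
}

oracle_chisq <- function(counts) {
  rtot <- rowSums(counts); ctot <- colSums(counts); tot <- sum(counts)
  stat <- 0
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    e <- rtot[i] * ctot[j] / tot
    stat <- stat + (counts[i, j] - e)^2 / e
  }
  stat
}

# A triangle-wave trial: contacts at both endpoints, known geometry.
triangle_trial <- function(amplitude = 40, period = 0.25, duration = 15,
                           rate = 100, id = "T1", task = "in_phase") {
  t <- seq(0, duration, by = 1 / rate)
  phase <- (t %% period) / period
  x <- amplitude * (2 * pmin(phase, 1 - phase))
  tapping_trial(id, task, rate, left = x, right = x, duration = duration)
}

# Constant-aperture trial (no taps at all).
flat_trial <- function(value = 40, id = "F1", task = "in_phase",
                       duration = 1, rate = 10) {
  n <- round(rate * duration) + 1
  tapping_trial(id, task, rate, left = rep(value, n), right = rep(value, n),
                duration = duration)
}

# Random single-subject profile for oracle-equivalence runs: one group
# cell filled with randomised but physiological parameters.
random_profiles <- function(seed) {
  withr::with_seed(seed, {
    p <- default_profiles()
    p$cells$interval_mean <- runif(12, 0.2, 0.6)
    p$cells$interval_sd <- runif(12, 0, 0.06)
    p$cells$amplitude_mean <- runif(12, 25, 60)
    p$cells$amplitude_sd <- runif(12, 0, 8)
    p$cells$fatigue_slope <- runif(12, -0.5, 0.3)
    p$phase$phase_sd <- runif(6, 2, 45)
    p
  })
}

# Minimal participant set for exclusion tests; trials are cheap 1 s flats.
mini_cohort <- function() {
  parts <- tibble::tibble(
    id = c("a", "b", "c", "d", "e"),
    age = c(20L, 70L, 80L, 45L, 21L),
    sex = c("female", "male", "female", "female", "male"),
    handedness = c("right", "right", "right", "right", "left"),
    mmse = c(NA, 28L, 23L, NA, NA)
  )
  trials <- unlist(lapply(parts$id, function(id) {
    lapply(TASKS <- c("in_phase", "anti_phase"), function(tk)
      flat_trial(40, id = id, task = tk))
  }), recursive = FALSE)
  cohort(parts, trials)
}
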