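# Local maxima of a series with plateau handling: a plateau counts once,
# at its first sample. Endpoints are never maxima.
local_maxima_idx <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  # run-length encode so plateaus collapse to single candidates
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  m <- length(r$values)
  if (m < 3) return(integer(0))
  k <- 2:(m - 1)
  is_max <- r$values[k] > r$values[k - 1] & r$values[k] > r$values[k + 1]
  starts[k][is_max]
}

# Topographic prominence of peak i: on each side, walk to the nearest
# strictly higher sample (or the series end) and take the minimum in
# between; prominence = peak - the higher of the two side minima.
peak_prominence <- function(x, idx) {
  vapply(idx, function(i) {
    v <- x[i]
    left <- x[seq_len(i - 1)]
    higher_l <- which(left > v)
    lo_l <- min(left[seq.int(from = if (length(higher_l)) max(higher_l) else 1,
                             to = i - 1)])
    right <- x[(i + 1):length(x)]
    higher_r <- which(right > v)
    lo_r <- min(right[seq.int(from = 1,
                              to = if (length(higher_r)) min(higher_r) else length(right))])
    v - max(lo_l, lo_r)
  }, numeric(1))
}

# Contact refinement. The distance waveform at a thumb-index contact is
# the junction of two open-close arches: value ~0, zero slope on both
# sides, but generally different curvature left and right of the contact
# (adjacent cycles differ in amplitude and duration). A single symmetric
# parabola fitted across the junction is pulled toward the flatter side,
# biasing contact times in proportion to the inter-hand lag; instead we
# fit y = y0 + a (t-t0)^2 [t < t0] + b (t-t0)^2 [t >= t0] with the vertex
# t0 profiled on a sub-sample grid (coarse-to-fine), which is unbiased
# under arch asymmetry.
junction_vertex <- function(time, x, i, half = 3L) {
  lo <- max(1L, i - half)
  hi <- min(length(x), i + half)
  if (hi - lo < 3L) return(c(time[i], x[i]))
  tt <- time[lo:hi]
  yy <- x[lo:hi]
  dt <- time[2] - time[1]
  sse_fit <- function(t0) {
    u <- (tt - t0)^2
    X <- cbind(1, u * (tt < t0), u * (tt >= t0))
    f <- stats::lm.fit(X, yy)
    c(sum(f$residuals^2), f$coefficients[1])
  }
  centre <- time[i]
  width <- dt
  best <- c(Inf, centre, x[i])
  for (pass in 1:2) {
    grid <- seq(centre - width, centre + width, length.out = 9)
    for (t0 in grid) {
      r <- sse_fit(t0)
      if (r[1] < best[1]) best <- c(r[1], t0, r[2])
    }
    centre <- best[2]
    width <- width / 4
  }
  if (!is.finite(best[3])) return(c(time[i], x[i]))
  c(best[2], best[3])
}

# Least-squares quadratic vertex through up to 2*half+1 samples around
# index i; returns c(time, value). Falls back to the sample itself when
# the fit is degenerate or the vertex escapes the window.
quad_vertex <- function(time, x, i, half = 2L) {
  lo <- max(1L, i - half)
  hi <- min(length(x), i + half)
  if (hi - lo < 2L) return(c(time[i], x[i]))
  tt <- time[lo:hi] - time[i]
  yy <- x[lo:hi]
  fit <- stats::lm.fit(cbind(1, tt, tt^2), yy)
  b <- fit$coefficients
  if (!is.finite(b[3]) || abs(b[3]) < 1e-12) return(c(time[i], x[i]))
  tv <- -b[2] / (2 * b[3])
  if (abs(tv) > (time[hi] - time[lo]) / 2) return(c(time[i], x[i]))
  c(time[i] + tv, b[1] - b[2]^2 / (4 * b[3]))
}

#' Detect tap events in one distance channel
#'
#' Peaks are local maxima with topographic prominence of at least
#' `min_prominence` (default 4 mm, 10% of the 40 mm target aperture;
#' plateaus resolve to their first sample). A tap event is the minimum
#' sample between each consecutive peak pair -- the thumb-index contact.
#' With `refine = TRUE` (the default) contact and peak coordinates are
#' interpolated to sub-sample resolution by a local least-squares
#' quadratic fit, which removes most of the sampling-grid quantisation
#' from interval and phase estimates.
#'
#' @param channel Numeric distance series (mm).
#' @param sampling_rate Sampling rate in Hz.
#' @param min_prominence Minimum peak prominence in mm (> 0).
#' @param refine Logical; sub-sample refinement of times/values.
#' @return A tibble of tap events with columns `contact_time`,
#'   `contact_value`, `prev_peak_time`, `prev_peak_value`,
#'   `next_peak_time`, `next_peak_value`. Zero rows when fewer than two
#'   prominent peaks exist.
#' @export
detect_taps <- function(channel, sampling_rate, min_prominence = 4,
                        refine = TRUE) {
  if (length(channel) < 3) stop("series too short", call. = FALSE)
  if (!is.numeric(min_prominence) || min_prominence <= 0) {
    stop("min_prominence must be > 0", call. = FALSE)
  }
  empty <- tibble::tibble(
    contact_time = numeric(0), contact_value = numeric(0),
    prev_peak_time = numeric(0), prev_peak_value = numeric(0),
    next_peak_time = numeric(0), next_peak_value = numeric(0)
  )
  time <- (seq_along(channel) - 1) / sampling_rate
  idx <- local_maxima_idx(channel)
  if (length(idx) < 2) return(empty)
  idx <- idx[peak_prominence(channel, idx) >= min_prominence]
  if (length(idx) < 2) return(empty)

  peak_coord <- if (refine) {
    t(vapply(idx, function(i) quad_vertex(time, channel, i), numeric(2)))
  } else {
    cbind(time[idx], channel[idx])
  }

  events <- lapply(seq_len(length(idx) - 1), function(k) {
    span <- (idx[k] + 1):(idx[k + 1] - 1)
    if (!length(span)) span <- idx[k]
    j <- span[which.min(channel[span])]
    cc <- if (refine) junction_vertex(time, channel, j)
          else c(time[j], channel[j])
    c(cc, peak_coord[k, ], peak_coord[k + 1, ])
  })
  ev <- do.call(rbind, events)
  tibble::tibble(
    contact_time = ev[, 1], contact_value = ev[, 2],
    prev_peak_time = ev[, 3], prev_peak_value = ev[, 4],
    next_peak_time = ev[, 5], next_peak_value = ev[, 6]
  )
}

#' Total traveling distance of one channel
#'
#' Sum of absolute sample-to-sample changes of the aperture distance: the
#' overall amount of finger movement during the trial.
#'
#' @param channel Numeric distance series (mm), length >= 2.
#' @return Distance in mm.
#' @examples
#' total_traveling_distance(c(0, 10, 40, 10, 0))  # 80
#' @export
total_traveling_distance <- function(channel) {
  if (length(channel) < 2) stop("need at least 2 samples", call. = FALSE)
  sum(abs(diff(channel)))
}

# The deduplicated peak list of a tap-event table, ordered by time.
tap_peaks <- function(taps) {
  pk <- rbind(cbind(taps$prev_peak_time, taps$prev_peak_value),
              cbind(taps$next_peak_time, taps$next_peak_value))
  pk <- pk[!duplicated(pk[, 1]), , drop = FALSE]
  pk[order(pk[, 1]), , drop = FALSE]
}

#' Local-maximum amplitude statistics
#'
#' Mean and sample SD of the per-cycle peak apertures, plus the ordinary
#' least-squares slope of peak value against peak time. A negative slope
#' reflects amplitude decay under fatigue; with no fatigue the slope is 0.
#'
#' @param taps Tap-event table from [detect_taps()].
#' @return List with `ave_local_max` (mm), `sd_local_max` (mm) and
#'   `slope` (mm/s); all `NA` when fewer than two distinct peaks exist.
#' @export
local_max_stats <- function(taps) {
  pk <- tap_peaks(taps)
  if (nrow(pk) < 2) {
    return(list(ave_local_max = NA_real_, sd_local_max = NA_real_,
                slope = NA_real_))
  }
  tt <- pk[, 1]; vv <- pk[, 2]
  slope <- sum((tt - mean(tt)) * (vv - mean(vv))) / sum((tt - mean(tt))^2)
  list(ave_local_max = mean(vv), sd_local_max = stats::sd(vv), slope = slope)
}

#' Tap count and interval statistics
#'
#' @param taps Tap-event table from [detect_taps()].
#' @return List with `number_of_taps`, `ave_tapping_interval` (s),
#'   `frequency_of_taps` (Hz, the inverse of the mean interval) and
#'   `sd_inter_tapping_interval` (s); the interval statistics are `NA`
#'   when fewer than two events exist.
#' @export
tap_interval_stats <- function(taps) {
  n <- nrow(taps)
  if (n < 2) {
    return(list(number_of_taps = n, ave_tapping_interval = NA_real_,
                frequency_of_taps = NA_real_,
                sd_inter_tapping_interval = NA_real_))
  }
  gaps <- diff(taps$contact_time)
  ave <- mean(gaps)
  list(number_of_taps = n, ave_tapping_interval = ave,
       frequency_of_taps = 1 / ave,
       sd_inter_tapping_interval = stats::sd(gaps))
}

wrap180 <- function(deg) {
  out <- (deg + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}

# Circular SD sqrt(-2 log rho) with the small-sample correction
# rho^2 = (n R^2 - 1)/(n - 1): for iid directions E[R^2] = 1/n +
# (1 - 1/n) rho^2 exactly, so the raw resultant length overestimates
# concentration (and underestimates spread) at the 20-60 cycles a 15 s
# trial yields.
circular_sd_deg <- function(deg) {
  n <- length(deg)
  rad <- deg * pi / 180
  R2 <- mean(cos(rad))^2 + mean(sin(rad))^2
  rho2 <- if (n > 1) max((n * R2 - 1) / (n - 1), 0) else R2
  if (rho2 <= 0) return(Inf)
  if (rho2 >= 1) return(0)
  sqrt(-log(rho2)) * 180 / pi
}

#' Inter-hand phase-difference variability
#'
#' With the right hand as the reference, each right-hand cycle
#' `c_k = r_(k+1) - r_k` is mapped to 360 degrees. The left-hand contact
#' nearest the task target (the right contact for in-phase, the cycle
#' midpoint for anti-phase) gives the lag angle
#' `360 (t_left - r_k) / c_k`, wrapped to (-180, 180] around the target
#' (0 or 180 degrees). The returned value is the circular standard
#' deviation of these angles, in degrees. Cycles with no left contact
#' within the cycle or its immediate neighbours are skipped.
#'
#' @param left_taps,right_taps Tap-event tables from [detect_taps()].
#' @param task `"in_phase"` or `"anti_phase"`.
#' @return Circular SD in degrees, or `NA` when fewer than 3 events per
#'   hand or no usable cycle exists.
#' @export
phase_difference_sd <- function(left_taps, right_taps, task) {
  task <- match.arg(task, TASKS)
  if (nrow(left_taps) < 3 || nrow(right_taps) < 3) return(NA_real_)
  r <- right_taps$contact_time
  l <- left_taps$contact_time
  target_deg <- if (task == "in_phase") 0 else 180
  dev <- numeric(0)
  for (k in seq_len(length(r) - 1)) {
    ck <- r[k + 1] - r[k]
    tgt <- r[k] + if (task == "in_phase") 0 else ck / 2
    cand <- l[l >= r[k] - ck & l <= r[k + 1] + ck]
    if (!length(cand)) next
    tl <- cand[which.min(abs(cand - tgt))]
    ang <- 360 * (tl - r[k]) / ck
    dev <- c(dev, wrap180(ang - target_deg))
  }
  if (!length(dev)) return(NA_real_)
  circular_sd_deg(dev)
}

#' Extract the nine coordination parameters from a trial
#'
#' Runs tap detection on both channels and composes the per-hand distance
#' and interval parameters plus the per-trial phase-difference SD.
#' Parameters that cannot be computed (too few taps) are returned as `NA`,
#' never as silent zeros.
#'
#' @param trial A [tapping_trial()].
#' @param min_prominence Peak prominence threshold in mm.
#' @param refine Sub-sample refinement flag, see [detect_taps()].
#' @return A tibble in long format with columns `participant_id`, `task`,
#'   `hand` (`left` / `right` / `both` for the phase row), `parameter`,
#'   `value`.
#' @export
extract_features <- function(trial, min_prominence = 4, refine = TRUE) {
  stopifnot(inherits(trial, "tapping_trial"))
  taps <- lapply(setNames(HANDS, HANDS), function(h) {
    detect_taps(trial[[h]], trial$sampling_rate, min_prominence, refine)
  })
  per_hand <- dplyr::bind_rows(lapply(HANDS, function(h) {
    lm <- local_max_stats(taps[[h]])
    ti <- tap_interval_stats(taps[[h]])
    tibble::tibble(
      hand = h,
      parameter = PARAMETERS[1:8],
      value = c(total_traveling_distance(trial[[h]]),
                lm$ave_local_max, lm$sd_local_max, lm$slope,
                ti$number_of_taps, ti$ave_tapping_interval,
                ti$frequency_of_taps, ti$sd_inter_tapping_interval)
    )
  }))
  phase <- tibble::tibble(
    hand = "both", parameter = "sd_phase_difference",
    value = phase_difference_sd(taps$left, taps$right, trial$task)
  )
  out <- dplyr::bind_rows(per_hand, phase)
  out$participant_id <- trial$participant_id
  out$task <- trial$task
  out[, c("participant_id", "task", "hand", "parameter", "value")]
}

#' Extract features for every trial of a cohort
#'
#' @param x A [cohort()] or a list of trials.
#' @inheritParams extract_features
#' @return Long-format tibble, one block of 17 rows per trial.
#' @export
extract_cohort_features <- function(x, min_prominence = 4, refine = TRUE) {
  trials <- if (inherits(x, "cohort")) x$trials else x
  dplyr::bind_rows(lapply(trials, extract_features,
                          min_prominence = min_prominence, refine = refine))
}
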