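#' Assign the gerontological age group
#'
#' Maps an integer age in years onto the three study strata: young adults
#' (18-22), young-old adults (65-74) and old-old adults (75 and above).
#' Ages outside every stratum are not part of the screened population and
#' are flagged for exclusion rather than silently dropped.
#'
#' @param age Integer age in years (vectorised).
#' @return Character vector with elements `"YA"`, `"YOA"`, `"OOA"` or
#'   `"age_out_of_range"`.
#' @examples
#' assign_age_group(c(20, 45, 75))
#' @export
assign_age_group <- function(age) {
  if (length(age) == 0) return(character(0))
  if (any(is.na(age))) stop("age must not be missing", call. = FALSE)
  if (!is.numeric(age) || any(age < 0) || any(age != round(age))) {
    stop("age must be a non-negative integer", call. = FALSE)
  }
  out <- rep("age_out_of_range", length(age))
  out[age >= 18 & age <= 22] <- "YA"
  out[age >= 65 & age <= 74] <- "YOA"
  out[age >= 75] <- "OOA"
  out
}

#' Construct a tapping trial object
#'
#' A trial is one 15-second recording of the thumb-index aperture distance
#' of both hands, sampled at a fixed rate. Channel lengths must equal
#' `round(sampling_rate * duration) + 1` and distances must be non-negative.
#'
#' @param participant_id Participant identifier.
#' @param task `"in_phase"` or `"anti_phase"`.
#' @param sampling_rate Sampling rate in Hz.
#' @param left,right Numeric distance series in mm.
#' @param duration Trial duration in seconds (default 15).
#' @return An object of class `tapping_trial`.
#' @export
tapping_trial <- function(participant_id, task, sampling_rate, left, right,
                          duration = 15) {
  task <- match.arg(task, TASKS)
  n_expect <- round(sampling_rate * duration) + 1
  if (length(left) != length(right)) {
    stop("left and right channels differ in length", call. = FALSE)
  }
  if (length(left) != n_expect) {
    stop(sprintf("channel length %d does not match round(rate x duration) + 1 = %d",
                 length(left), n_expect), call. = FALSE)
  }
  if (any(!is.finite(left)) || any(!is.finite(right))) {
    stop("non-finite distance values", call. = FALSE)
  }
  if (any(left < 0) || any(right < 0)) {
    stop("distances must be >= 0", call. = FALSE)
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      task = task,
      sampling_rate = sampling_rate,
      duration = duration,
      time = seq(0, duration, by = 1 / sampling_rate),
      left = as.numeric(left),
      right = as.numeric(right)
    ),
    class = "tapping_trial"
  )
}

#' @export
print.tapping_trial <- function(x, ...) {
  cat(sprintf(
    "<tapping_trial> participant %s, %s task, %.0f Hz, %.1f s (%d samples/channel)\n",
    x$participant_id, x$task, x$sampling_rate, x$duration, length(x$left)
  ))
  invisible(x)
}

#' Maximum aperture amplitude of a trial
#'
#' The device-based exclusion rule flags recordings whose distance reaches
#' 300 mm or more (a sensor artefact at the UB-2's working range); the
#' maximum is taken over both channels of the trial.
#'
#' @param trial A [tapping_trial()].
#' @return Maximum distance in mm.
#' @export
max_amplitude <- function(trial) {
  stopifnot(inherits(trial, "tapping_trial"))
  if (length(trial$left) == 0 || length(trial$right) == 0) {
    stop("empty channel", call. = FALSE)
  }
  max(trial$left, trial$right)
}

#' Assemble a cohort object
#'
#' @param participants Tibble with columns `id`, `age`, `sex`, `handedness`,
#'   `mmse` (NA allowed for young adults) and optionally `disorder` (logical
#'   pre-screening flag) and `group`.
#' @param trials List of [tapping_trial()] objects.
#' @param exclusion_log Tibble of `(participant_id, reason)` rows.
#' @return An object of class `cohort`.
#' @export
cohort <- function(participants, trials,
                   exclusion_log = tibble::tibble(participant_id = character(0),
                                                  reason = character(0))) {
  participants <- tibble::as_tibble(participants)
  req <- c("id", "age", "sex", "handedness", "mmse")
  miss <- setdiff(req, names(participants))
  if (length(miss)) stop("participants missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(participants$id)) stop("duplicate participant ids", call. = FALSE)
  structure(
    list(participants = participants, trials = trials,
         exclusion_log = tibble::as_tibble(exclusion_log)),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d trials, %d exclusions logged\n",
              nrow(x$participants), length(x$trials), nrow(x$exclusion_log)))
  invisible(x)
}

trials_for <- function(trials, id) {
  trials[vapply(trials, function(t) t$participant_id == id, logical(1))]
}

#' Apply the participant exclusion rules
#'
#' Screens a cohort with the study's exclusion criteria, applied in a fixed
#' order so the log is deterministic: pre-screened disorder flag (when the
#' `disorder` column is present), left-handedness, maximum aperture of
#' 300 mm or more on any trial, incomplete trials (anything other than one
#' trial per task), age outside the recruited bands, and -- for the older
#' groups only -- an MMSE score of 23 or less. Only the first matching
#' reason is logged per participant. The operation is idempotent.
#'
#' @param x A [cohort()].
#' @return A `cohort` containing only the kept participants and their
#'   trials, with all removals appended to `exclusion_log`.
#' @export
apply_exclusions <- function(x) {
  stopifnot(inherits(x, "cohort"))
  p <- x$participants
  reasons <- rep(NA_character_, nrow(p))

  if ("disorder" %in% names(p)) {
    flag <- !is.na(p$disorder) & as.logical(p$disorder)
    reasons[is.na(reasons) & flag] <- "disorder"
  }
  reasons[is.na(reasons) & p$handedness == "left"] <- "left_handed"

  amp_flag <- vapply(p$id, function(id) {
    tr <- trials_for(x$trials, id)
    length(tr) > 0 && any(vapply(tr, max_amplitude, numeric(1)) >= 300)
  }, logical(1))
  reasons[is.na(reasons) & amp_flag] <- "amplitude_ge_300"

  complete_flag <- vapply(p$id, function(id) {
    tr <- trials_for(x$trials, id)
    tasks <- vapply(tr, function(t) t$task, character(1))
    length(tr) == 2 && setequal(tasks, TASKS) && !anyDuplicated(tasks)
  }, logical(1))
  reasons[is.na(reasons) & !complete_flag] <- "incomplete_trials"

  grp <- assign_age_group(p$age)
  reasons[is.na(reasons) & grp == "age_out_of_range"] <- "age_out_of_range"

  older <- is.na(reasons) & grp %in% c("YOA", "OOA")
  if (any(older & is.na(p$mmse))) {
    stop("missing MMSE for older participant(s): ",
         paste(p$id[older & is.na(p$mmse)], collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(p$mmse) & (p$mmse < 0 | p$mmse > 30))) {
    stop("MMSE out of 0-30 range", call. = FALSE)
  }
  reasons[older & p$mmse <= 23] <- "mmse_le_23"

  keep <- is.na(reasons)
  kept <- p[keep, , drop = FALSE]
  kept$group <- assign_age_group(kept$age)
  kept_trials <- x$trials[vapply(x$trials, function(t)
    t$participant_id %in% kept$id, logical(1))]
  log_new <- tibble::tibble(participant_id = p$id[!keep],
                            reason = reasons[!keep])
  cohort(kept, kept_trials,
         exclusion_log = dplyr::bind_rows(x$exclusion_log, log_new))
}

#' Write / read a single trial
#'
#' Trials are stored as a plain-text CSV (`time_s,left_mm,right_mm`) plus a
#' JSON sidecar carrying `participant_id`, `task`, `sampling_rate_hz` and
#' `duration_s`. The sidecar shares the CSV path with extension `.json`.
#' Values round-trip at the written precision (6 decimal places, i.e.
#' 1 nm -- far below sensor resolution).
#'
#' @param trial A [tapping_trial()].
#' @param path CSV file path.
#' @return `write_trial` returns `path` invisibly; `read_trial` returns a
#'   `tapping_trial`.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "tapping_trial"))
  df <- data.frame(time_s = round(trial$time, 6),
                   left_mm = round(trial$left, 6),
                   right_mm = round(trial$right, 6))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(participant_id = trial$participant_id, task = trial$task,
               sampling_rate_hz = trial$sampling_rate,
               duration_s = trial$duration)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' @rdname write_trial
#' @param path CSV file path; the JSON sidecar must sit next to it.
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("no such trial file: ", path, call. = FALSE)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing JSON sidecar: ", sp, call. = FALSE)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  req <- c("participant_id", "task", "sampling_rate_hz", "duration_s")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("sidecar missing keys: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "left_mm", "right_mm") %in% names(df))) {
    stop("trial CSV must have header time_s,left_mm,right_mm", call. = FALSE)
  }
  if (anyNA(df$left_mm) || anyNA(df$right_mm)) {
    stop("trial channels contain missing values (unequal lengths?)", call. = FALSE)
  }
  if (any(df$left_mm < 0) || any(df$right_mm < 0)) {
    stop("negative distances in trial file", call. = FALSE)
  }
  tapping_trial(meta$participant_id, meta$task, meta$sampling_rate_hz,
                left = df$left_mm, right = df$right_mm,
                duration = meta$duration_s)
}

#' Write / read cohort participant metadata
#'
#' Plain CSV with header `id,age,sex,handedness,mmse`.
#'
#' @param participants Participant tibble.
#' @param path CSV path.
#' @export
write_cohort_meta <- function(participants, path) {
  cols <- c("id", "age", "sex", "handedness", "mmse")
  utils::write.csv(as.data.frame(participants)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_meta
#' @export
read_cohort_meta <- function(path) {
  df <- utils::read.csv(path, colClasses = c(id = "character"))
  req <- c("id", "age", "sex", "handedness", "mmse")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("cohort CSV missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tibble::as_tibble(df)
}
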