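#' Binarise coordination performance into screening states
#'
#' The age-cutoff ROC uses a binary "low performance" state as the
#' condition and age as the predictor. The default rule is a whole-sample
#' median split in the parameter's "worse" direction, with ties assigned
#' to the better class: for parameters where larger is better (travel
#' distance, average local maximum distance, number and frequency of taps)
#' the positive state is value < median, otherwise value > median. The
#' alternative rule `"young_ref_1sd"` marks values worse than the
#' young-adult mean by more than one young-adult SD.
#'
#' @param values Numeric parameter values.
#' @param parameter Parameter id (one of the nine coordination parameters).
#' @param rule `"median"` or `"young_ref_1sd"`.
#' @param young_values Young-group values, required for `"young_ref_1sd"`.
#' @return Integer vector of states (1 = low performance).
#' @export
binarize_performance <- function(values, parameter, rule = c("median", "young_ref_1sd"),
                                 young_values = NULL) {
  rule <- match.arg(rule)
  if (!parameter %in% names(PARAMETER_HIGHER_BETTER)) {
    stop("unknown parameter direction: ", parameter, call. = FALSE)
  }
  hb <- PARAMETER_HIGHER_BETTER[[parameter]]
  if (rule == "median") {
    m <- stats::median(values)
    as.integer(if (hb) values < m else values > m)
  } else {
    if (is.null(young_values)) {
      stop("young_values required for rule 'young_ref_1sd'", call. = FALSE)
    }
    mu <- mean(young_values); s <- stats::sd(young_values)
    as.integer(if (hb) values < mu - s else values > mu + s)
  }
}

#' Nonparametric (Mann-Whitney) AUC
#'
#' Probability that a randomly chosen positive-state subject has a higher
#' predictor value than a negative-state subject, ties counted one half:
#' `(concordant + 0.5 x ties) / (n1 x n0)`.
#'
#' @param predictor Numeric predictor (age in the screening analysis).
#' @param states 0/1 state labels (1 = positive, low performance).
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(predictor, states) {
  states <- as.integer(states)
  if (length(predictor) != length(states)) stop("length mismatch", call. = FALSE)
  n1 <- sum(states == 1); n0 <- sum(states == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty", call. = FALSE)
  r <- rank(predictor)
  (sum(r[states == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hanley-McNeil standard error of the AUC
#'
#' Closed-form SE of the nonparametric AUC estimator:
#' `SE^2 = (A(1-A) + (n1-1)(Q1-A^2) + (n0-1)(Q2-A^2)) / (n1 n0)` with
#' `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param auc AUC estimate in `[0, 1]`.
#' @param n_pos,n_neg Class sizes (both >= 2).
#' @return Standard error.
#' @export
auc_se_hanley_mcneil <- function(auc, n_pos, n_neg) {
  if (auc < 0 || auc > 1) stop("auc must be in [0, 1]", call. = FALSE)
  if (n_pos < 2 || n_neg < 2) stop("need at least 2 per class", call. = FALSE)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Normal-approximation 95% confidence interval for the AUC
#'
#' `auc +/- 1.96 x se`, clipped to `[0, 1]`.
#'
#' @param auc AUC estimate.
#' @param se Standard error (>= 0).
#' @return Numeric `c(lower, upper)`.
#' @export
ci95 <- function(auc, se) {
  if (se < 0) stop("se must be >= 0", call. = FALSE)
  c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se))
}

#' Youden-index optimal cutoff
#'
#' Scans thresholds at midpoints between adjacent distinct predictor
#' values (classifying positive when predictor >= threshold) and returns
#' the threshold maximising sensitivity + specificity - 1; ties break
#' toward the lower threshold. With integer ages this yields the familiar
#' half-year cutoffs.
#'
#' @inheritParams auc_mann_whitney
#' @return List with `cutoff`, `sensitivity`, `specificity`,
#'   `youden_index`.
#' @export
youden_cutoff <- function(predictor, states) {
  states <- as.integer(states)
  n1 <- sum(states == 1); n0 <- sum(states == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty", call. = FALSE)
  v <- sort(unique(predictor))
  if (length(v) < 2) stop("predictor has a single distinct value", call. = FALSE)
  thr <- (utils::head(v, -1) + utils::tail(v, -1)) / 2
  best <- list(yi = -Inf)
  for (th in thr) {
    sn <- sum(predictor >= th & states == 1) / n1
    sp <- sum(predictor < th & states == 0) / n0
    yi <- sn + sp - 1
    if (yi > best$yi + 1e-12) best <- list(cutoff = th, sn = sn, sp = sp, yi = yi)
  }
  list(cutoff = best$cutoff, sensitivity = best$sn,
       specificity = best$sp, youden_index = best$yi)
}

#' Parameters eligible for the age-cutoff ROC panel
#'
#' The screening panel is restricted to parameters whose post-hoc
#' contrasts separate all three age groups in both tasks. Given a
#' Bonferroni post-hoc table covering group contrasts per task slice,
#' returns the parameter ids meeting that condition; the published panel
#' comprises `number_of_taps`, `ave_tapping_interval` and
#' `frequency_of_taps`.
#'
#' @param posthoc Post-hoc tibble from [bonferroni_posthoc()] (rows for
#'   group contrasts with `slice` of the form `task=...`).
#' @param alpha Significance level.
#' @return Character vector of parameter ids.
#' @export
eligible_roc_parameters <- function(posthoc, alpha = 0.05) {
  group_contrasts <- vapply(pairs_of(GROUPS), paste, "", collapse = " vs ")
  ph <- posthoc[grepl(" vs ", posthoc$contrast) &
                posthoc$contrast %in% group_contrasts, ]
  if (!nrow(ph)) return(character(0))
  ok <- vapply(unique(ph$parameter), function(pm) {
    d <- ph[ph$parameter == pm, ]
    all(vapply(TASKS, function(tk) {
      # task-sliced contrasts (from a task x group interaction) when
      # available, otherwise the group main-effect family applies to both
      # tasks
      dd <- d[d$slice == paste0("task=", tk), ]
      if (!nrow(dd)) dd <- d[d$slice == "-", ]
      nrow(dd) == 3 && all(dd$p_adj < alpha)
    }, logical(1)))
  }, logical(1))
  unique(ph$parameter)[ok]
}

#' Age-cutoff ROC panel
#'
#' For each requested (parameter, task, hand) cell: binarise performance
#' with `rule`, use age as predictor of the low-performance state, and
#' report the Mann-Whitney AUC, its Hanley-McNeil SE, the normal p-value
#' against AUC = 0.5, the 95% CI, and the Youden-index age cutoff with
#' sensitivity/specificity (as percentages).
#'
#' @param features Long feature tibble.
#' @param meta Participant metadata (needs `id`, `age`).
#' @param parameters Parameter ids to screen; defaults to the published
#'   panel. Parameters outside `eligible` are skipped with a warning.
#' @param rule Binarisation rule, see [binarize_performance()].
#' @param eligible Character vector of eligible parameter ids, e.g. from
#'   [eligible_roc_parameters()]; defaults to the published panel.
#' @return Tibble with one row per (parameter, task, hand).
#' @export
run_roc_panel <- function(features, meta, parameters = ROC_PARAMETERS,
                          rule = "median", eligible = ROC_PARAMETERS) {
  bad <- setdiff(parameters, eligible)
  if (length(bad)) {
    warning("skipping ineligible parameter(s): ", paste(bad, collapse = ", "),
            call. = FALSE)
    parameters <- intersect(parameters, eligible)
  }
  tab <- analysis_table(features, meta)
  rows <- list()
  for (pm in parameters) {
    for (tk in TASKS) {
      for (h in HANDS) {
        d <- tab[tab$parameter == pm & tab$task == tk & tab$hand == h, ]
        d <- d[stats::complete.cases(d[, c("age", "value")]), ]
        young <- d$value[d$group == "YA"]
        st <- binarize_performance(d$value, pm, rule, young_values = young)
        auc <- auc_mann_whitney(d$age, st)
        se <- auc_se_hanley_mcneil(auc, sum(st == 1), sum(st == 0))
        ci <- ci95(auc, se)
        yj <- youden_cutoff(d$age, st)
        p <- if (se == 0) 0 else 2 * stats::pnorm(-abs(auc - 0.5) / se)
        rows[[length(rows) + 1]] <- tibble::tibble(
          parameter = pm, task = tk, hand = h,
          auc = auc, auc_se = se, p = p,
          cutoff = yj$cutoff, ci_low = ci[1], ci_high = ci[2],
          sensitivity = 100 * yj$sensitivity,
          specificity = 100 * yj$specificity,
          youden_index = yj$youden_index,
          n_pos = sum(st == 1), n_neg = sum(st == 0),
          rule = rule
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Published UB-2 screening reference values
#'
#' The published age-cutoff table for the UB-2 bimanual tapping screening
#' study (12 rows: three parameters x two tasks x two hands), shipped as
#' a plain-text reference dataset. Used to validate the arithmetic
#' identities of the ROC summaries (Youden index = Sn + Sp - 1;
#' CI = AUC +/- 1.96 SE).
#'
#' @return Tibble with columns `parameter`, `task`, `hand`, `auc`,
#'   `auc_sd`, `cutoff_years`, `ci_low`, `ci_high`, `sn_pct`, `sp_pct`,
#'   `yi`.
#' @export
reference_cutoffs <- function() {
  path <- system.file("extdata", "reference_cutoffs.csv", package = "bimotap",
                      mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path))
}
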