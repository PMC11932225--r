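#' Pearson chi-square test on a contingency table of counts
#'
#' Plain Pearson chi-square without continuity correction, as used to
#' compare male/female ratios across the three age groups.
#'
#' @param counts Numeric matrix of counts, at least 2 x 2.
#' @return List with `statistic`, `df` and `p`.
#' @examples
#' chi_square_counts(rbind(c(25, 72), c(17, 85), c(52, 170)))
#' @export
chi_square_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("need at least a 2x2 table", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

# Reshape one parameter of a long feature table to one row per subject,
# columns = within-factor cells, and check balance.
anova_wide <- function(data, parameter, within) {
  d <- data[data$parameter == parameter, , drop = FALSE]
  if (!nrow(d)) stop("parameter not present: ", parameter, call. = FALSE)
  d <- d[stats::complete.cases(d[, c("participant_id", "group", within, "value")]), ]
  cell <- do.call(paste, c(lapply(within, function(w) d[[w]]), sep = "|"))
  d$cell <- cell
  cells <- sort(unique(cell))
  wide <- tidyr::pivot_wider(
    d[, c("participant_id", "group", "cell", "value")],
    names_from = "cell", values_from = "value"
  )
  bad <- wide$participant_id[!stats::complete.cases(wide)]
  if (length(bad)) {
    stop("incomplete within-subject cells for: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ...", call. = FALSE)
  }
  list(wide = wide, cells = cells)
}

effect_table <- function(ut) {
  keep <- setdiff(rownames(ut), "(Intercept)")
  tibble::tibble(
    effect = keep,
    F = unname(ut[keep, "F value"]),
    df1 = unname(ut[keep, "num Df"]),
    df2 = unname(ut[keep, "den Df"]),
    p = unname(ut[keep, "Pr(>F)"])
  )
}

#' Mixed-design analysis of variance
#'
#' Between-subject factor `group` crossed with the within-subject factors
#' given in `within` (any subset of `hand` and `task`, both with two
#' levels, so no sphericity correction is required). Sums of squares are
#' Type III with sum-to-zero contrasts on the group factor, matching the
#' SPSS GLM repeated-measures convention; the test is the univariate
#' mixed-model F from the multivariate linear model
#' ([car::Anova()] with an intra-subject design).
#'
#' @param data Long tibble with columns `participant_id`, `group`,
#'   `value`, `parameter` and the within-factor columns.
#' @param parameter Which parameter to analyse.
#' @param within Character vector of within-subject factors; `character(0)`
#'   degenerates to a one-way between-groups ANOVA.
#' @return Tibble with one row per effect: `effect`, `F`, `df1`, `df2`, `p`.
#' @export
mixed_anova <- function(data, parameter, within = c("hand", "task")) {
  data$group <- factor(data$group, levels = intersect(GROUPS, unique(data$group)))
  if (length(within) == 0) {
    d <- data[data$parameter == parameter, , drop = FALSE]
    d <- d[stats::complete.cases(d[, c("group", "value")]), ]
    mod <- stats::lm(value ~ group, data = d,
                     contrasts = list(group = "contr.sum"))
    a <- car::Anova(mod, type = 3)
    return(tibble::tibble(
      effect = "group",
      F = a["group", "F value"], df1 = a["group", "Df"],
      df2 = a["Residuals", "Df"], p = a["group", "Pr(>F)"]
    ))
  }
  aw <- anova_wide(data, parameter, within)
  wide <- aw$wide
  Y <- as.matrix(wide[, aw$cells])
  grp <- factor(wide$group, levels = levels(data$group))
  idata <- as.data.frame(do.call(rbind, strsplit(aw$cells, "|", fixed = TRUE)),
                         stringsAsFactors = FALSE)
  names(idata) <- within
  for (w in within) idata[[w]] <- factor(idata[[w]])
  mod <- if (nlevels(droplevels(grp)) < 2) {
    stats::lm(Y ~ 1)
  } else {
    stats::lm(Y ~ grp, contrasts = list(grp = "contr.sum"))
  }
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  av <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
  ut <- summary(av, multivariate = FALSE)$univariate.tests
  et <- effect_table(ut)
  et$effect <- gsub("grp", "group", et$effect)
  et
}

#' @rdname mixed_anova
#' @details `two_way_mixed_anova()` is the phase-difference variant with
#'   `task` as the only within factor.
#' @export
two_way_mixed_anova <- function(data, parameter = "sd_phase_difference") {
  mixed_anova(data, parameter, within = "task")
}

pairs_of <- function(lv) {
  if (length(lv) < 2) return(list())
  cmb <- utils::combn(lv, 2, simplify = FALSE)
  cmb
}

posthoc_one_family <- function(d, factor_name, paired, slice_label) {
  lv <- if (factor_name == "group") intersect(GROUPS, unique(d[[factor_name]]))
        else intersect(c(HANDS, TASKS), unique(d[[factor_name]]))
  fam <- pairs_of(lv)
  k <- length(fam)
  dplyr::bind_rows(lapply(fam, function(pr) {
    a <- d$value[d[[factor_name]] == pr[1]]
    b <- d$value[d[[factor_name]] == pr[2]]
    tt <- if (paired) {
      ia <- d$participant_id[d[[factor_name]] == pr[1]]
      ib <- d$participant_id[d[[factor_name]] == pr[2]]
      stopifnot(identical(ia, ib))
      stats::t.test(a, b, paired = TRUE)
    } else {
      stats::t.test(a, b, var.equal = TRUE)
    }
    est <- mean(a) - mean(b)
    tibble::tibble(
      slice = slice_label, contrast = paste(pr[1], "vs", pr[2]),
      estimate = est,
      direction = paste(pr[which.min(c(mean(a), mean(b)))], "<",
                        pr[which.max(c(mean(a), mean(b)))]),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value, family = k,
      p_adj = pmin(1, tt$p.value * k)
    )
  }))
}

#' Bonferroni post-hoc contrasts for a significant ANOVA effect
#'
#' For a main effect, all pairwise contrasts of that factor's levels
#' (independent t tests for `group`, paired t tests for within factors),
#' each value first averaged over the remaining within-subject cells per
#' subject. For a two-way interaction `A:B`, the simple effects: pairwise
#' contrasts of each factor within every level of the other. Adjusted
#' p-values are `min(1, raw p x family size)` with the family being the
#' contrasts sharing one slice.
#'
#' @param data Long tibble as for [mixed_anova()].
#' @param parameter Parameter to test.
#' @param effect Effect label as returned by [mixed_anova()] (e.g.
#'   `"group"`, `"task:group"`).
#' @param effects Optional effect table from [mixed_anova()]; when given,
#'   the call is refused unless `effect` is significant at `alpha`.
#' @param alpha Significance level (default 0.05).
#' @param force Run even without a significance record (used for
#'   simulation studies).
#' @return Tibble of contrasts with raw and Bonferroni-adjusted p-values.
#' @export
bonferroni_posthoc <- function(data, parameter, effect, effects = NULL,
                               alpha = 0.05, force = FALSE) {
  if (!force) {
    if (is.null(effects)) {
      stop("supply the effect table (or force = TRUE)", call. = FALSE)
    }
    row <- effects[effects$effect %in% c(effect, rev_effect(effect)), ]
    if (!nrow(row)) stop("effect not found: ", effect, call. = FALSE)
    if (all(row$p >= alpha)) {
      stop("effect '", effect, "' is not significant (p = ",
           signif(min(row$p), 3), "); post-hoc refused", call. = FALSE)
    }
  }
  d <- data[data$parameter == parameter, , drop = FALSE]
  d <- d[stats::complete.cases(d[, c("participant_id", "value")]), ]
  fac <- strsplit(effect, ":", fixed = TRUE)[[1]]
  subject_mean <- function(dd, keep) {
    dd %>%
      dplyr::group_by(dplyr::across(dplyr::all_of(c("participant_id", "group", keep)))) %>%
      dplyr::summarise(value = mean(.data$value), .groups = "drop")
  }
  if (length(fac) == 1) {
    dm <- subject_mean(d, setdiff(fac, "group"))
    dm <- dplyr::arrange(dm, .data$participant_id)
    out <- posthoc_one_family(dm, fac, paired = fac != "group", slice_label = "-")
  } else if (length(fac) == 2) {
    out <- dplyr::bind_rows(lapply(seq_along(fac), function(i) {
      f_test <- fac[i]; f_slice <- fac[-i]
      dm <- subject_mean(d, unique(c(setdiff(c(f_test, f_slice), "group"))))
      dm <- dplyr::arrange(dm, .data$participant_id)
      dplyr::bind_rows(lapply(sort(unique(dm[[f_slice]])), function(sl) {
        posthoc_one_family(dm[dm[[f_slice]] == sl, ], f_test,
                           paired = f_test != "group",
                           slice_label = paste0(f_slice, "=", sl))
      }))
    }))
  } else {
    stop("post-hoc supported for main effects and two-way interactions",
         call. = FALSE)
  }
  out$parameter <- parameter
  out$effect <- effect
  out[, c("parameter", "effect", "slice", "contrast", "estimate",
          "direction", "t", "df", "p_raw", "family", "p_adj")]
}

rev_effect <- function(effect) {
  paste(rev(strsplit(effect, ":", fixed = TRUE)[[1]]), collapse = ":")
}

#' Pearson correlations between age and every parameter cell
#'
#' One correlation per (task, hand, parameter) combination, participant
#' age against parameter value.
#'
#' @param data Long tibble with `participant_id`, `age`, `task`, `hand`,
#'   `parameter`, `value`.
#' @return Tibble with `task`, `hand`, `parameter`, `r`, `p`, `n`; cells
#'   with fewer than 3 complete pairs or zero variance carry `NA`.
#' @export
pearson_age_correlations <- function(data) {
  d <- data[stats::complete.cases(data[, c("age", "value")]), ]
  combos <- dplyr::distinct(d[, c("task", "hand", "parameter")])
  dplyr::bind_rows(lapply(seq_len(nrow(combos)), function(i) {
    cc <- combos[i, ]
    dd <- d[d$task == cc$task & d$hand == cc$hand &
            d$parameter == cc$parameter, ]
    n <- nrow(dd)
    if (n < 3 || stats::sd(dd$age) == 0 || stats::sd(dd$value) == 0) {
      return(tibble::tibble(task = cc$task, hand = cc$hand,
                            parameter = cc$parameter,
                            r = NA_real_, p = NA_real_, n = n))
    }
    ct <- stats::cor.test(dd$age, dd$value)
    tibble::tibble(task = cc$task, hand = cc$hand, parameter = cc$parameter,
                   r = unname(ct$estimate), p = ct$p.value, n = n)
  }))
}

#' Join features with participant metadata into the analysis table
#'
#' @param features Long feature tibble from [extract_cohort_features()].
#' @param meta Participant tibble (needs `id`, `age`, `sex`; `group` is
#'   derived from age when absent).
#' @return Long tibble with group/age/sex merged in.
#' @export
analysis_table <- function(features, meta) {
  meta <- tibble::as_tibble(meta)
  if (!"group" %in% names(meta)) meta$group <- assign_age_group(meta$age)
  dplyr::left_join(features,
                   meta[, c("id", "group", "age", "sex")],
                   by = c(participant_id = "id"))
}
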