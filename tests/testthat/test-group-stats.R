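test_that("Pearson chi-square matches the closed form and is permutation invariant", {
  # published sex counts: no significant male/female imbalance
  counts <- rbind(c(25, 72), c(17, 85), c(52, 170))
  r <- chi_square_counts(counts)
  expect_equal(r$statistic, oracle_chisq(counts), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_gt(r$p, 0.05)
  # homogeneous table
  h <- chi_square_counts(rbind(c(10, 10), c(10, 10)))
  expect_equal(h$statistic, 0)
  expect_equal(h$p, 1)
  # random tables vs brute-force expected-counts loop; row/col permutations
  set.seed(31)
  for (i in 1:15) {
    m <- matrix(rpois(6, 30) + 1, nrow = 3)
    expect_equal(chi_square_counts(m)$statistic, oracle_chisq(m),
                 tolerance = 1e-10)
    expect_equal(chi_square_counts(m[sample(3), sample(2)])$statistic,
                 chi_square_counts(m)$statistic, tolerance = 1e-10)
  }
  expect_error(chi_square_counts(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(chi_square_counts(matrix(1:3, 1)), "2x2")
})

make_long <- function(n_per_group, means = NULL, sd = 1, seed = 1,
                      subject_sd = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (g in c("YA", "YOA", "OOA")) {
      for (i in seq_len(n_per_group)) {
        id <- paste0(g, i)
        u <- rnorm(1, 0, subject_sd)
        for (tk in c("in_phase", "anti_phase")) for (h in c("left", "right")) {
          mu <- if (is.null(means)) 0 else means[[g]][[tk]][[h]]
          rows[[length(rows) + 1]] <- tibble::tibble(
            participant_id = id, group = g, task = tk, hand = h,
            parameter = "y", value = mu + u + rnorm(1, 0, sd))
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

test_that("degenerate between-only call reproduces the hand-computed one-way F", {
  d <- tibble::tibble(
    participant_id = as.character(1:6),
    group = rep(c("YA", "YOA"), each = 3),
    parameter = "y", value = c(1, 2, 3, 4, 5, 6)
  )
  et <- mixed_anova(d, "y", within = character(0))
  expect_equal(et$F, 13.5, tolerance = 1e-12)
  expect_equal(c(et$df1, et$df2), c(1, 4))
})

test_that("three-way mixed ANOVA has the right effects and matches paired t", {
  d <- make_long(12, seed = 8)
  et <- mixed_anova(d, "y")
  expect_setequal(et$effect,
                  c("group", "hand", "task", "group:hand", "group:task",
                    "hand:task", "group:hand:task"))
  expect_true(all(et$F >= 0))
  expect_true(all(et$p >= 0 & et$p <= 1))
  # within-factor F (2 levels) equals the squared paired t on differences,
  # when no between factor competes: single-group data
  d1 <- d[d$group == "YA", ]
  et1 <- mixed_anova(d1, "y")
  wide <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(d1, participant_id, task),
                     value = mean(value), .groups = "drop"),
    names_from = task, values_from = value)
  tt <- t.test(wide$in_phase - wide$anti_phase)
  expect_equal(et1$F[et1$effect == "task"], unname(tt$statistic)^2,
               tolerance = 1e-8)
  expect_equal(et1$p[et1$effect == "task"], tt$p.value, tolerance = 1e-8)
  # missing cells are refused with the offending subject named
  expect_error(mixed_anova(d[-1, ], "y"), "incomplete.*YA1")
})

test_that("constant input never produces spurious significance", {
  d <- make_long(6, seed = 2)
  d$value <- 5
  et <- suppressWarnings(two_way_mixed_anova(
    dplyr::summarise(dplyr::group_by(d, participant_id, group, task),
                     value = mean(value), .groups = "drop") |>
      dplyr::mutate(parameter = "sd_phase_difference")))
  expect_true(all(is.na(et$p) | et$p >= 0.05 | et$F == 0))
})

test_that("two-way mixed ANOVA isolates an injected task effect", {
  means <- list()
  for (g in c("YA", "YOA", "OOA")) {
    means[[g]] <- list(in_phase = list(left = 0, right = 0),
                       anti_phase = list(left = 1.5, right = 1.5))
  }
  d <- make_long(15, means = means, seed = 21)
  d$parameter <- "sd_phase_difference"
  d <- dplyr::summarise(dplyr::group_by(d, participant_id, group, task, parameter),
                        value = mean(value), .groups = "drop")
  et <- two_way_mixed_anova(d)
  expect_lt(et$p[et$effect == "task"], 0.01)
  expect_gt(et$p[et$effect == "group"], 0.001)  # no group effect injected
  expect_setequal(et$effect, c("group", "task", "group:task"))
})

test_that("Bonferroni adjustment is the definition and respects the gate", {
  means <- list(YA = list(in_phase = list(left = 0, right = 0),
                          anti_phase = list(left = 0, right = 0)),
                YOA = list(in_phase = list(left = 1, right = 1),
                           anti_phase = list(left = 1, right = 1)),
                OOA = list(in_phase = list(left = 2, right = 2),
                           anti_phase = list(left = 2, right = 2)))
  d <- make_long(15, means = means, seed = 5, subject_sd = 0.3)
  et <- mixed_anova(d, "y")
  ph <- bonferroni_posthoc(d, "y", "group", effects = et)
  expect_equal(unique(ph$family), 3)
  expect_equal(ph$p_adj, pmin(1, ph$p_raw * 3))
  expect_true(all(ph$p_adj >= ph$p_raw))
  expect_equal(nrow(ph), 3)
  # row order of the input does not change the result
  ph2 <- bonferroni_posthoc(d[sample(nrow(d)), ], "y", "group", effects = et)
  expect_equal(dplyr::arrange(ph2, contrast)$p_adj,
               dplyr::arrange(ph, contrast)$p_adj, tolerance = 1e-12)
  # refusal on a non-significant effect
  null_d <- make_long(8, seed = 400)
  null_et <- mixed_anova(null_d, "y")
  weakest <- null_et$effect[which.max(null_et$p)]
  expect_error(bonferroni_posthoc(null_d, "y", weakest, effects = null_et),
               "not significant")
  # interaction: simple effects within each slice, family = 3 per group slice
  phi <- bonferroni_posthoc(d, "y", "group:task", effects = et, force = TRUE)
  expect_true(all(grepl("=", phi$slice)))
  expect_equal(unique(phi$family[grepl("task=", phi$slice)]), 3)
})

test_that("age correlations match the covariance oracle and flag degeneracy", {
  d <- tibble::tibble(
    participant_id = as.character(1:6), age = c(20, 30, 40, 50, 60, 70),
    task = "in_phase", hand = "right", parameter = "y",
    value = c(6, 5, 4, 3, 2, 1))
  r <- pearson_age_correlations(d)
  expect_equal(r$r, -1, tolerance = 1e-12)
  set.seed(77)
  for (i in 1:10) {
    d$value <- rnorm(6)
    r <- pearson_age_correlations(d)
    num <- sum((d$age - mean(d$age)) * (d$value - mean(d$value)))
    den <- sqrt(sum((d$age - mean(d$age))^2) * sum((d$value - mean(d$value))^2))
    expect_equal(r$r, num / den, tolerance = 1e-12)
  }
  d$value <- 3
  expect_true(is.na(pearson_age_correlations(d)$r))
})

test_that("null data reject each ANOVA effect at close to the nominal rate", {
  # quick calibration check (the full 500-replicate audit lives in the
  # acceptance suite); 150 replicates, pooled over effects
  reject <- c()
  for (s in 1:150) {
    d <- make_long(8, seed = 9000 + s)
    et <- mixed_anova(d, "y")
    reject <- c(reject, et$p < 0.05)
  }
  rate <- mean(reject)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.08)
})
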