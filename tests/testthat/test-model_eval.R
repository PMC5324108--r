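test_that("crude odds ratios match exhaustive 2x2 computation", {
  expect_equal(crude_or(10, 10, 10, 10)$or, 1)
  set.seed(51)
  for (i in 1:25) {
    cts <- sample(1:500, 4, replace = TRUE)
    res <- crude_or(cts[1], cts[2], cts[3], cts[4])
    expect_equal(res$or, (cts[1] * cts[4]) / (cts[2] * cts[3]))
    manual_se <- sqrt(sum(1 / cts))
    expect_equal(res$conf.low, res$or * exp(-stats::qnorm(0.975) * manual_se))
  }
  expect_error(crude_or(0, 5, 5, 5), "zero cell")
  expect_error(crude_or(1.5, 5, 5, 5), "whole numbers")
})

test_that("the rank AUROC equals brute-force pair concordance", {
  set.seed(52)
  for (i in 1:10) {
    n <- sample(50:500, 1)
    y <- rbinom(n, 1, 0.4)
    if (!any(y == 1) || !any(y == 0)) next
    score <- sample(1:20, n, replace = TRUE)   # heavy ties
    expect_equal(auroc(score, y), auroc_pairs(score, y))
  }
})

test_that("the rank AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(53)
  y <- rbinom(300, 1, 0.5)
  score <- rnorm(300) + y
  reference <- as.numeric(pROC::auc(pROC::roc(y, score, quiet = TRUE)))
  expect_equal(auroc(score, y), reference, tolerance = 1e-10)
})

test_that("the stratified AUROC reduces and averages as designed", {
  d <- null_cohort(400, 800, seed = 54)
  pooled <- auroc(d$score, d$case_status)
  one <- ps_stratified_auroc(d, score, n_strata = 1)
  expect_equal(one$estimate, pooled, tolerance = 1e-12)
  expect_equal(one$method, "plain")

  # perfect ranking within every stratum
  perfect <- dplyr::mutate(d, score = as.integer(case_status == "case"))
  expect_equal(ps_stratified_auroc(perfect, score)$estimate, 1)

  # null scores at scale: within 3 SE of 0.5
  big <- null_cohort(6666, 13334, seed = 55)
  est <- ps_stratified_auroc(big, score)$estimate
  n1 <- 6666; n0 <- 13334
  se_null <- sqrt((n1 + n0 + 1) / (12 * n1 * n0)) * sqrt(5)  # 5 strata
  expect_lt(abs(est - 0.5), 3 * se_null)
})

test_that("degenerate propensity strata are handled per design", {
  d <- tibble::tibble(
    case_status = rep(c("case", "control"), c(10, 40)),
    score = rnorm(50),
    ps = c(rep(5, 10), seq(-5, 0, length.out = 40))  # top stratum all cases
  )
  expect_error(suppressWarnings(ps_stratified_auroc(d, score)),
               "no controls")

  d2 <- tibble::tibble(
    case_status = rep(c("control", "case", "control"), c(40, 10, 10)),
    score = rnorm(60),
    ps = c(seq(-10, -1, length.out = 40), rnorm(20))
  )
  warnings <- testthat::capture_warnings(
    res <- ps_stratified_auroc(d2, score)
  )
  expect_true(any(grepl("no cases", warnings)))
  expect_true(res$estimate >= 0 && res$estimate <= 1)
})

test_that("cross-validated AUROC is null without signal and reproducible", {
  d <- null_cohort(300, 600, seed = 56) |>
    dplyr::mutate(x1 = rnorm(900), x2 = rnorm(900))
  cv1 <- cv_auroc(d, terms = c("x1", "x2"), n_boot = 0, seed = 57)
  cv2 <- cv_auroc(d, terms = c("x1", "x2"), n_boot = 0, seed = 57)
  expect_identical(cv1, cv2)
  expect_lt(abs(cv1$estimate - 0.5), 0.05)
  expect_error(cv_auroc(d[1:10, ], terms = "x1", k = 8, n_boot = 0),
               "Too few")
})

test_that("bootstrap confidence intervals bracket the point estimate", {
  cohort <- make_scored_cohort(seed = 58)
  res <- cv_auroc(cohort, k = 5, n_boot = 25, seed = 59)
  expect_true(res$conf.low <= res$estimate && res$estimate <= res$conf.high)
  expect_true(res$conf.low >= 0 && res$conf.high <= 1)
})

test_that("cross-validation removes optimism on average", {
  cfg <- cohort_config(n_cases = 100, n_controls = 200, n_regions = 2,
                       pool_factor = 4)
  n_rep <- 50
  diffs <- vapply(seq_len(n_rep), function(r) {
    cohort <- make_scored_cohort(cfg, seed = 600 + r)
    cv <- cv_auroc(cohort, n_boot = 0, seed = 600 + r)$estimate
    ap <- apparent_auroc(cohort)$estimate
    ap - cv
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("the factor-level model recovers each per-factor effect", {
  cohort <- make_scored_cohort(cohort_config(n_cases = 1000,
                                             n_controls = 2000,
                                             n_regions = 4), seed = 61)
  factors <- c("alcohol_high", "obese", "no_physical_activity",
               "low_vegetables", "high_red_meat", "no_nsaid_asa")
  fit <- fit_risk_model(cohort, terms = c(factors, "family_history", "grs"))
  est <- tidy(fit)
  rows <- est[est$term %in% factors, ]
  # every factor generated with a common OR of 1.36
  expect_true(all(rows$conf.low < 1.36 * 1.25 & rows$conf.high > 1.36 / 1.25))
  expect_error(fit_risk_model(cohort, terms = "not_a_column"), "requires")
})

test_that("separation aborts with diagnostics", {
  d <- tibble::tibble(
    case_status = rep(c("case", "control"), each = 30),
    x = c(rnorm(30, 10), rnorm(30, -10)),
    ps = rnorm(60, 0, 0.01)
  )
  expect_error(fit_risk_model(d, terms = "x"), "separation")
})

test_that("screening sensitivity falls and specificity rises with the cutoff", {
  cohort <- make_scored_cohort(seed = 62)
  cuts <- c(0.25, 0.5, 1, 2, 4)
  perf <- screening_performance(cohort, cuts)
  expect_equal(perf$cutoff, cuts)
  expect_true(all(diff(perf$sensitivity) <= 0))
  expect_true(all(diff(perf$specificity) >= 0))
  # a cutoff below every score is all-positive
  low <- screening_performance(cohort, min(cohort$rs) - 1)
  expect_equal(low$sensitivity, 100)
  expect_equal(low$specificity, 0)
  expect_false(low$negative_lr_defined)
  high <- screening_performance(cohort, max(cohort$rs) + 1)
  expect_false(high$positive_lr_defined)
})

test_that("the cumulative AUROC curve orders variables and reaches the full model", {
  cohort <- make_scored_cohort(cohort_config(n_cases = 400, n_controls = 800,
                                             n_regions = 3), seed = 63)
  single <- cumulative_auroc_curve(cohort, vars = "grs", seed = 64)
  expect_equal(single$individual_auroc, single$cumulative_auroc)

  curve <- cumulative_auroc_curve(
    cohort, vars = c("ers", "family_history", "grs"), seed = 65
  )
  expect_equal(sort(curve$individual_auroc), curve$individual_auroc)
  full <- cv_auroc(cohort, terms = c("ers", "family_history", "grs"),
                   n_boot = 0, seed = 66)$estimate
  expect_lt(abs(dplyr::last(curve$cumulative_auroc) - full), 0.03)
})

test_that("pure-noise variables do not add cross-validated discrimination", {
  cfg <- cohort_config(n_cases = 150, n_controls = 300, n_regions = 2,
                       pool_factor = 4)
  n_rep <- 15
  gains <- vapply(seq_len(n_rep), function(r) {
    cohort <- make_scored_cohort(cfg, seed = 700 + r)
    cohort$noise <- rnorm(nrow(cohort))
    base <- cv_auroc(cohort, terms = c("ers", "family_history", "grs"),
                     n_boot = 0, seed = 700 + r)$estimate
    plus <- cv_auroc(cohort, terms = c("ers", "family_history", "grs",
                                       "noise"),
                     n_boot = 0, seed = 700 + r)$estimate
    plus - base
  }, numeric(1))
  expect_lt(mean(gains), 2 * stats::sd(gains) / sqrt(n_rep) + 1e-8)
})
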