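test_that("degenerate allele frequencies give constant genotypes", {
  sexes <- rep(c("male", "female"), 10)
  g0 <- simulate_genotypes(tiny_panel(raf = c(0, 0, 0)), 20, sexes, seed = 1)
  expect_true(all(as.matrix(g0) == 0))
  g1 <- simulate_genotypes(tiny_panel(raf = c(1, 1, 1)), 20, sexes, seed = 1)
  expect_true(all(g1$rsA1 == 2) && all(g1$rsA2 == 2))
  expect_true(all(g1$rsX1[sexes == "male"] == 1))
  expect_true(all(g1$rsX1[sexes == "female"] == 2))
})

test_that("autosomal genotypes match the binomial expectation and HWE", {
  n <- 10000
  p <- 0.3
  g <- simulate_genotypes(tiny_panel(raf = c(p, p, p)), n,
                          rep("female", n), seed = 42)
  se_mean <- sqrt(2 * p * (1 - p) / n)
  expect_lt(abs(mean(g$rsA1) - 2 * p), 3 * se_mean)
  # genotype class frequencies vs (1-p)^2, 2p(1-p), p^2
  expected <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  observed <- tabulate(g$rsA2 + 1, nbins = 3) / n
  for (k in 1:3) {
    se_k <- sqrt(expected[k] * (1 - expected[k]) / n)
    expect_lt(abs(observed[k] - expected[k]), 4 * se_k)
  }
})

test_that("invalid genotype simulation inputs are rejected", {
  expect_error(simulate_genotypes(tiny_panel(raf = c(-0.1, 0.5, 0.5)),
                                  5, rep("male", 5)), "probability")
  expect_error(simulate_genotypes(tiny_panel(), 5, rep("other", 5)), "sexes")
})

test_that("risk factors follow configured prevalences", {
  cfg0 <- small_config(factor_prevalences = c(
    alcohol_high = 0, obese = 0, no_physical_activity = 0,
    low_vegetables = 0, high_red_meat = 0, no_nsaid_asa = 0
  ))
  f0 <- simulate_risk_factors(cfg0, 200, seed = 1)
  expect_true(all(f0$alcohol_high == 0) && all(f0$no_nsaid_asa == 0))

  cfg1 <- small_config(factor_prevalences = c(
    alcohol_high = 1, obese = 1, no_physical_activity = 1,
    low_vegetables = 1, high_red_meat = 1, no_nsaid_asa = 1
  ))
  f1 <- compute_ers(simulate_risk_factors(cfg1, 200, seed = 1))
  expect_true(all(f1$ers == 6))

  # family-history prevalence at the calibrated 12.14%
  f <- simulate_risk_factors(small_config(), 50000, seed = 7)
  se <- sqrt(0.1214 * (1 - 0.1214) / 50000)
  expect_lt(abs(mean(f$family_history) - 0.1214), 3 * se)
})

test_that("outcome assignment follows the generating logistic model", {
  cfg_null <- small_config(or_per_factor = 1, or_fh = 1, or_per_allele = 1,
                           baseline_logit = -1)
  n <- 20000
  pool <- dplyr::bind_cols(
    simulate_risk_factors(cfg_null, n, seed = 3),
    simulate_genotypes(tiny_panel(), n, rep("female", n))
  )
  out <- assign_outcomes(pool, cfg_null, tiny_panel())
  p0 <- plogis(-1)
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(out$case_status == "case") - p0), 3 * se)

  # exact logistic identity: one extra ERS unit multiplies the odds by OR_E
  cfg <- small_config()
  two <- tibble::tibble(
    alcohol_high = c(0L, 1L), obese = 0L, no_physical_activity = 0L,
    low_vegetables = 0L, high_red_meat = 0L, no_nsaid_asa = 0L,
    family_history = 0L, rsA1 = 1L, rsA2 = 1L, rsX1 = 1L
  )
  p <- case_probability(two, cfg, tiny_panel())
  odds <- p / (1 - p)
  expect_equal(odds[2] / odds[1], cfg$or_per_factor, tolerance = 1e-12)
})

test_that("frequency matching draws the right controls per stratum", {
  one_stratum <- function(n, status) tibble::tibble(
    case_status = status, sex = "male", region = "R01",
    age = rep(52, n)
  )
  matched <- frequency_match(one_stratum(10, "case"),
                             one_stratum(100, "control"),
                             ratio = 2, seed = 1)
  expect_equal(sum(matched$case_status == "control"), 20)

  expect_error(
    frequency_match(one_stratum(2, "case"),
                    one_stratum(5, "control")[0, ], ratio = 2),
    "No eligible controls"
  )
})

test_that("simulated cohorts satisfy the matching rule", {
  cohort <- simulate_cohort(small_config(), seed = 5)
  stratum <- paste(cohort$sex, cohort$region, 5 * floor(cohort$age / 5))
  case_strata <- unique(stratum[cohort$case_status == "case"])
  control_strata <- unique(stratum[cohort$case_status == "control"])
  expect_true(all(case_strata %in% control_strata))
  expect_equal(sum(cohort$case_status == "case"), 150)
  ratio <- sum(cohort$case_status == "control") /
    sum(cohort$case_status == "case")
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("cohort generation is reproducible for a fixed seed", {
  a <- simulate_cohort(small_config(), seed = 99)
  b <- simulate_cohort(small_config(), seed = 99)
  expect_identical(a, b)
})

test_that("missingness injection hits the configured rates only", {
  cohort <- simulate_cohort(small_config(), seed = 2)
  expect_identical(inject_missing(cohort, c(bmi = 0), seed = 1), cohort)

  all_gone <- inject_missing(cohort, c(bmi = 1), seed = 1)
  expect_true(all(is.na(all_gone$bmi)))
  expect_identical(all_gone[setdiff(names(cohort), "bmi")],
                   cohort[setdiff(names(cohort), "bmi")])

  big <- tibble::tibble(subject_id = as.character(1:10000),
                        case_status = "control", age = 50, sex = "male",
                        region = "R01", bmi = rnorm(10000, 25))
  rate <- 0.05
  masked <- inject_missing(big, c(bmi = rate), seed = 3)
  se <- sqrt(rate * (1 - rate) / 10000)
  expect_lt(abs(mean(is.na(masked$bmi)) - rate), 3 * se)

  expect_error(inject_missing(cohort, c(age = 0.1)), "Design variables")
})

test_that("refitting the generating model recovers the true effects", {
  # interval-coverage property across replicates at reduced size
  n_rep <- 100
  truth <- c(ers = log(1.36), family_history = log(2.25), grs = log(1.07))
  covered <- matrix(FALSE, n_rep, 3, dimnames = list(NULL, names(truth)))
  cfg <- cohort_config(n_cases = 300, n_controls = 600, n_regions = 4,
                       pool_factor = 4)
  for (r in seq_len(n_rep)) {
    cohort <- make_scored_cohort(cfg, seed = 1000 + r)
    est <- tidy(fit_risk_model(cohort), exponentiate = FALSE)
    est <- est[match(names(truth), est$term), ]
    covered[r, ] <- est$conf.low <= truth & truth <= est$conf.high
  }
  coverage <- colMeans(covered)
  expect_true(all(coverage >= 0.90),
              label = paste("CI coverage:",
                            paste(round(coverage, 2), collapse = ", ")))
})
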