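#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Autosomal genotypes are allele counts drawn Binomial(2, p) at the panel
#' risk-allele frequency. The X-linked variant is drawn Binomial(2, p) for
#' females and Binomial(1, p) for males (hemizygous, values 0/1).
#'
#' @param panel A [snp_panel()].
#' @param n Number of subjects.
#' @param sexes Character vector of length `n` with values `"male"`/`"female"`.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so callers can manage reproducibility themselves).
#' @return A tibble with one 0/1/2 column per variant, named by rsid.
#' @export
simulate_genotypes <- function(panel, n, sexes, seed = NULL) {
  panel <- snp_panel(panel)
  n <- assert_count(n, "n")
  if (length(sexes) != n || !all(sexes %in% c("male", "female"))) {
    abort("`sexes` must be length `n` with values \"male\"/\"female\".")
  }
  if (!is.null(seed)) set.seed(seed)
  male <- sexes == "male"
  cols <- purrr::pmap(
    list(panel$rsid, panel$chromosome, panel$raf),
    function(rsid, chr, p) {
      if (identical(chr, "X")) {
        g <- integer(n)
        g[male] <- rbinom(sum(male), 1L, p)
        g[!male] <- rbinom(sum(!male), 2L, p)
        g
      } else {
        rbinom(n, 2L, p)
      }
    }
  )
  names(cols) <- panel$rsid
  tibble::as_tibble(cols)
}

#' Simulate binary risk factors and family history
#'
#' Independent Bernoulli draws at the configured prevalences (the six
#' modifiable factors, family history, and ever-smoking).
#'
#' @param config A [cohort_config()].
#' @param n Number of subjects.
#' @inheritParams simulate_genotypes
#' @return A tibble of 0/1 columns.
#' @export
simulate_risk_factors <- function(config, n, seed = NULL) {
  config <- validate_cohort_config(unclass(config))
  n <- assert_count(n, "n")
  if (!is.null(seed)) set.seed(seed)
  prev <- config$factor_prevalences
  out <- purrr::map(prev, ~ rbinom(n, 1L, .x))
  out$family_history <- rbinom(n, 1L, config$fh_prevalence)
  out$smoker_ever <- rbinom(n, 1L, config$smoking_prevalence)
  tibble::as_tibble(out)
}

# Raw lifestyle variables consistent with the latent binary indicators, so
# that derive_risk_factors() on the simulated cohort recovers them exactly.
# Risk-side draws sit strictly inside the risk category (boundaries follow
# the scoring conventions: alcohol strict >, BMI inclusive >=30, vegetables
# inclusive <=200, red meat strict >65, activity exactly 0 MET).
synthesize_raw_variables <- function(factors, sexes) {
  n <- nrow(factors)
  thr <- ifelse(sexes == "male", 4, 2)
  alcohol <- ifelse(factors$alcohol_high == 1,
                    thr + rexp(n, rate = 1 / 1.5),
                    runif(n, 0, thr))
  bmi <- ifelse(factors$obese == 1,
                30 + rexp(n, rate = 1 / 3),
                runif(n, 18.5, 29.9))
  met <- ifelse(factors$no_physical_activity == 1,
                0,
                0.5 + rexp(n, rate = 1 / 12))
  red_meat <- ifelse(factors$high_red_meat == 1,
                     65 + rexp(n, rate = 1 / 40),
                     runif(n, 0, 65))
  vegetables <- ifelse(factors$low_vegetables == 1,
                       runif(n, 0, 200),
                       200 + rexp(n, rate = 1 / 80))
  smoking <- ifelse(factors$smoker_ever == 1,
                    sample(c("former", "current"), n, replace = TRUE),
                    "never")
  tibble::tibble(
    alcohol_sua_day = alcohol,
    bmi = bmi,
    met_h_week = met,
    red_meat_g_day = red_meat,
    vegetables_g_day = vegetables,
    nsaid_regular_use = 1L - factors$no_nsaid_asa,
    smoking_status = smoking
  )
}

#' Per-subject disease probability under the generating logistic model
#'
#' `P(case) = plogis(baseline_logit + log(OR_E) * ERS + log(OR_F) * FH +
#' log(OR_G) * GRS)` where ERS is the count of the six modifiable factors and
#' GRS the unweighted risk-allele count (X coded 0/0.5/1).
#'
#' @param pool A tibble with the six factor columns, `family_history`, and the
#'   panel genotype columns.
#' @param config A [cohort_config()].
#' @param panel A [snp_panel()].
#' @return A numeric vector of probabilities.
#' @export
case_probability <- function(pool, config, panel = default_snp_panel()) {
  config <- validate_cohort_config(unclass(config))
  factors <- names(config$factor_prevalences)
  assert_columns(pool, c(factors, "family_history"), "case_probability()")
  ers <- rowSums(pool[factors])
  grs <- compute_grs(pool, panel)$grs
  eta <- config$baseline_logit +
    log(config$or_per_factor) * ers +
    log(config$or_fh) * pool$family_history +
    log(config$or_per_allele) * grs
  plogis(eta)
}

#' Assign case/control outcomes from the generating logistic model
#'
#' @inheritParams case_probability
#' @inheritParams simulate_genotypes
#' @return `pool` with a `case_status` column (`"case"`/`"control"`).
#' @export
assign_outcomes <- function(pool, config, panel = default_snp_panel(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- case_probability(pool, config, panel)
  pool$case_status <- ifelse(rbinom(nrow(pool), 1L, p) == 1L,
                             "case", "control")
  pool
}

#' Frequency-match controls to cases
#'
#' Within each sex x region x 5-year-age-band stratum containing cases,
#' controls are sampled without replacement: `round(ratio * cases)` (at least
#' one) or all available if fewer. A stratum with cases but no eligible
#' controls is an error. The overall control:case ratio therefore
#' approximates `ratio`; leftover controls are discarded.
#'
#' @param cases Tibble of case rows (needs `sex`, `region`, `age`).
#' @param control_pool Tibble of candidate control rows.
#' @param ratio Target controls per case.
#' @param age_band_width Width of the matching age bands in years.
#' @inheritParams simulate_genotypes
#' @return A tibble binding the cases and the sampled controls.
#' @export
frequency_match <- function(cases, control_pool, ratio = 2,
                            age_band_width = 5, seed = NULL) {
  assert_positive(ratio, "ratio")
  for (d in list(cases, control_pool)) {
    assert_columns(d, c("sex", "region", "age"), "frequency_match()")
  }
  if (!is.null(seed)) set.seed(seed)
  stratum_of <- function(d) {
    paste(d$sex, d$region, age_band(d$age, age_band_width), sep = "|")
  }
  case_strata <- stratum_of(cases)
  ctrl_strata <- stratum_of(control_pool)
  picks <- lapply(unique(case_strata), function(s) {
    n_case <- sum(case_strata == s)
    avail <- which(ctrl_strata == s)
    if (!length(avail)) {
      abort(sprintf(
        "No eligible controls for stratum %s (%d case%s).",
        s, n_case, if (n_case > 1) "s" else ""
      ))
    }
    target <- max(1L, round(ratio * n_case))
    if (length(avail) == 1L) avail else sample(avail, min(target, length(avail)))
  })
  dplyr::bind_rows(cases, control_pool[sort(unlist(picks)), ])
}

#' Set fields missing completely at random
#'
#' Masks each targeted column independently at its configured rate. The design
#' variables (`subject_id`, `case_status`, `age`, `sex`, `region`) can never
#' be masked.
#'
#' @param data A cohort tibble.
#' @param rates Named vector of per-column missingness rates in \[0, 1\].
#' @inheritParams simulate_genotypes
#' @return `data` with `NA` injected.
#' @export
inject_missing <- function(data, rates, seed = NULL) {
  if (is.null(rates) || !length(rates)) return(data)
  assert_probability(rates, "rates")
  protected <- c("subject_id", "case_status", "age", "sex", "region")
  bad <- intersect(names(rates), protected)
  if (length(bad)) {
    abort(paste0("Design variables cannot be masked: ",
                 paste(bad, collapse = ", "), "."))
  }
  assert_columns(data, names(rates), "inject_missing()")
  if (!is.null(seed)) set.seed(seed)
  for (v in names(rates)) {
    data[[v]][runif(nrow(data)) < rates[[v]]] <- NA
  }
  data
}

#' Simulate a frequency-matched case-control cohort
#'
#' Generates a population pool (ages, sexes, regions, education, three
#' ancestry components, risk factors with consistent raw lifestyle variables,
#' HWE genotypes), assigns disease status from the configured logistic model,
#' samples the requested number of cases, and frequency-matches controls by
#' sex, region and 5-year age band. Output columns carry the raw variables;
#' binary risk indicators are recovered downstream with
#' [derive_risk_factors()].
#'
#' @param config A [cohort_config()].
#' @param panel A [snp_panel()].
#' @param seed Integer seed; the whole cohort is reproducible given the seed.
#' @return A tibble, one row per subject, genotype columns named by rsid.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_cases = 60, n_controls = 120,
#'                                         n_regions = 2), seed = 1)
#' table(cohort$case_status)
simulate_cohort <- function(config = cohort_config(),
                            panel = default_snp_panel(),
                            seed = NULL) {
  config <- validate_cohort_config(unclass(config))
  panel <- snp_panel(panel)
  if (!is.null(seed)) set.seed(seed)

  pool_n <- ceiling(config$pool_factor * (config$n_cases + config$n_controls))
  band <- sample(config$age_bands, pool_n, replace = TRUE,
                 prob = config$age_band_weights)
  age <- band + sample.int(5, pool_n, replace = TRUE) - 1L
  sex <- ifelse(runif(pool_n) < config$sex_ratio_male, "male", "female")
  region <- sample(sprintf("R%02d", seq_len(config$n_regions)), pool_n,
                   replace = TRUE)
  education <- sample(config$education_levels, pool_n, replace = TRUE,
                      prob = config$education_probs)
  factors <- simulate_risk_factors(config, pool_n)
  raw <- synthesize_raw_variables(factors, sex)
  genotypes <- simulate_genotypes(panel, pool_n, sex)

  pool <- dplyr::bind_cols(
    tibble::tibble(
      age = age, sex = sex, region = region, education = education,
      pc1 = rnorm(pool_n), pc2 = rnorm(pool_n), pc3 = rnorm(pool_n)
    ),
    factors, raw, genotypes
  )
  pool <- assign_outcomes(pool, config, panel)

  cases <- dplyr::filter(pool, .data$case_status == "case")
  controls <- dplyr::filter(pool, .data$case_status == "control")
  # Enrol only cases whose sex x region x age-band stratum holds at least one
  # eligible control, mirroring the matching rule of a frequency-matched study.
  stratum <- function(d) paste(d$sex, d$region, age_band(d$age), sep = "|")
  cases <- cases[stratum(cases) %in% unique(stratum(controls)), , drop = FALSE]
  if (nrow(cases) < config$n_cases) {
    abort(sprintf(
      paste0("Pool produced %d matchable cases but %d were requested; ",
             "increase `pool_factor` or raise `baseline_logit`."),
      nrow(cases), config$n_cases
    ))
  }
  cases <- dplyr::slice_sample(cases, n = config$n_cases)
  cohort <- frequency_match(cases, controls,
                            ratio = config$n_controls / config$n_cases)

  cohort$subject_id <- sprintf("S%05d", seq_len(nrow(cohort)))
  cohort <- dplyr::select(
    cohort, "subject_id", "case_status", "age", "sex", "region", "education",
    "pc1", "pc2", "pc3", "family_history",
    "alcohol_sua_day", "bmi", "met_h_week", "red_meat_g_day",
    "vegetables_g_day", "nsaid_regular_use", "smoking_status",
    dplyr::all_of(panel$rsid)
  )
  inject_missing(cohort, config$missing_rates)
}

#' Write / read a cohort in the tab-separated dialect
#'
#' One row per subject, header, missing values as empty fields, genotype
#' columns named by rsid.
#'
#' @param data A cohort tibble.
#' @param path File path.
#' @return `write_cohort()` returns `data` invisibly; `read_cohort()` a tibble.
#' @export
write_cohort <- function(data, path) {
  readr::write_tsv(data, path, na = "")
  invisible(data)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  readr::read_tsv(path, na = "", show_col_types = FALSE)
}
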