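#' Configuration of the synthetic case-control cohort generator
#'
#' The defaults encode the study conditions the package simulates: 1336 cases
#' frequency-matched to 2744 controls (by sex, region and 5-year age band),
#' six modifiable binary risk factors at the control prevalences of the
#' source case-control study, family history at 12.14% prevalence, genotypes
#' in Hardy-Weinberg equilibrium at the panel risk-allele frequencies, and a
#' logistic outcome model with odds ratios 1.36 per environmental factor,
#' 2.25 for family history, and 1.07 per risk allele.
#'
#' @param n_cases,n_controls Target numbers of cases and matched controls.
#' @param factor_prevalences Named vector of the six modifiable-factor
#'   prevalences (`alcohol_high`, `obese`, `no_physical_activity`,
#'   `low_vegetables`, `high_red_meat`, `no_nsaid_asa`), on the probability
#'   scale.
#' @param fh_prevalence Prevalence of family history of colorectal cancer.
#' @param smoking_prevalence Prevalence of ever-smoking (recorded but not part
#'   of the environmental risk score).
#' @param or_per_factor,or_fh,or_per_allele True odds ratios of the generating
#'   logistic model (per environmental factor, for family history, per risk
#'   allele).
#' @param baseline_logit Intercept of the generating logistic model, i.e. the
#'   log-odds of disease at ERS = 0, FH = 0, GRS = 0. The default of -2.8
#'   yields roughly 30% cases in the simulated population pool.
#' @param age_bands Starting ages of the 5-year bands subjects are drawn from.
#' @param age_band_weights Sampling weights over `age_bands` (any positive
#'   scale); the default skews towards 50-85 as in a colorectal-cancer study.
#' @param sex_ratio_male Proportion of males in the simulated pool.
#' @param n_regions Number of recruiting regions/centres.
#' @param education_levels,education_probs Levels and sampling probabilities
#'   of the education covariate.
#' @param missing_rates Optional named vector of per-column missingness rates
#'   applied to the finished cohort (design variables cannot be masked).
#' @param pool_factor The population pool simulated before case-control
#'   sampling has `pool_factor * (n_cases + n_controls)` subjects.
#' @return A validated list of class `cohort_config`.
#' @seealso [simulate_cohort()], [read_cohort_config()]
#' @export
cohort_config <- function(n_cases = 1336,
                          n_controls = 2744,
                          factor_prevalences = c(
                            alcohol_high = 0.1556,
                            obese = 0.0685,
                            no_physical_activity = 0.3852,
                            low_vegetables = 0.6917,
                            high_red_meat = 0.4093,
                            no_nsaid_asa = 0.2730
                          ),
                          fh_prevalence = 0.1214,
                          smoking_prevalence = 0.5645,
                          or_per_factor = 1.36,
                          or_fh = 2.25,
                          or_per_allele = 1.07,
                          baseline_logit = -2.8,
                          age_bands = seq(25, 80, by = 5),
                          age_band_weights = c(1.2, 1.2, 1.2, 1.2, 1.2,
                                               12.25, 12.25, 12.25, 12.25,
                                               15, 15, 15),
                          sex_ratio_male = 0.62,
                          n_regions = 12,
                          education_levels = c("primary", "secondary",
                                               "university"),
                          education_probs = c(0.5, 0.3, 0.2),
                          missing_rates = NULL,
                          pool_factor = 3) {
  config <- list(
    n_cases = assert_count(n_cases, "n_cases"),
    n_controls = assert_count(n_controls, "n_controls"),
    factor_prevalences = factor_prevalences,
    fh_prevalence = fh_prevalence,
    smoking_prevalence = smoking_prevalence,
    or_per_factor = or_per_factor,
    or_fh = or_fh,
    or_per_allele = or_per_allele,
    baseline_logit = baseline_logit,
    age_bands = age_bands,
    age_band_weights = age_band_weights,
    sex_ratio_male = sex_ratio_male,
    n_regions = assert_count(n_regions, "n_regions"),
    education_levels = education_levels,
    education_probs = education_probs,
    missing_rates = missing_rates,
    pool_factor = pool_factor
  )
  validate_cohort_config(config)
}

validate_cohort_config <- function(config) {
  required <- c("alcohol_high", "obese", "no_physical_activity",
                "low_vegetables", "high_red_meat", "no_nsaid_asa")
  if (!all(required %in% names(config$factor_prevalences))) {
    abort(paste0("`factor_prevalences` must name all six factors: ",
                 paste(required, collapse = ", "), "."))
  }
  config$factor_prevalences <- config$factor_prevalences[required]
  assert_probability(config$factor_prevalences, "factor_prevalences")
  assert_probability(config$fh_prevalence, "fh_prevalence")
  assert_probability(config$smoking_prevalence, "smoking_prevalence")
  assert_probability(config$sex_ratio_male, "sex_ratio_male")
  assert_positive(config$or_per_factor, "or_per_factor")
  assert_positive(config$or_fh, "or_fh")
  assert_positive(config$or_per_allele, "or_per_allele")
  if (!is.finite(config$baseline_logit)) abort("`baseline_logit` must be finite.")
  if (length(config$age_band_weights) != length(config$age_bands)) {
    abort("`age_band_weights` must have one weight per age band.")
  }
  assert_positive(config$age_band_weights, "age_band_weights")
  if (length(config$education_probs) != length(config$education_levels)) {
    abort("`education_probs` must match `education_levels`.")
  }
  assert_probability(config$education_probs, "education_probs")
  assert_positive(config$pool_factor, "pool_factor")
  if (!is.null(config$missing_rates)) {
    if (is.null(names(config$missing_rates)) ||
        any(names(config$missing_rates) == "")) {
      abort("`missing_rates` must be a named vector of per-column rates.")
    }
    assert_probability(config$missing_rates, "missing_rates")
  }
  structure(config, class = "cohort_config")
}

#' Read a generator configuration from a YAML file
#'
#' Keys mirror the arguments of [cohort_config()]; unspecified keys keep their
#' defaults. A packaged default is at
#' `system.file("extdata", "default_config.yaml", package = "crcrisk")`.
#'
#' @param path Path to a YAML file.
#' @return A validated `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  values <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(values), known)
  if (length(unknown)) {
    abort(paste0("Unknown configuration keys: ",
                 paste(unknown, collapse = ", "), "."))
  }
  for (key in c("factor_prevalences", "missing_rates")) {
    if (!is.null(values[[key]])) values[[key]] <- unlist(values[[key]])
  }
  for (key in c("age_bands", "age_band_weights", "education_probs")) {
    if (!is.null(values[[key]])) values[[key]] <- as.numeric(unlist(values[[key]]))
  }
  do.call(cohort_config, values)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  cases/controls: %d / %d (pool x%.1f)\n",
              x$n_cases, x$n_controls, x$pool_factor))
  cat(sprintf("  true ORs: %.3f per factor, %.3f family history, %.3f per allele\n",
              x$or_per_factor, x$or_fh, x$or_per_allele))
  cat(sprintf("  baseline logit: %.2f; %d regions; %.0f%% male\n",
              x$baseline_logit, x$n_regions, 100 * x$sex_ratio_male))
  invisible(x)
}
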