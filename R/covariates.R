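#' Cut-offs defining the binary risk indicators
#'
#' Boundary conventions: alcohol strictly above the sex-specific threshold
#' (>4 standard units/day in men, >2 in women); obesity inclusive
#' (BMI >= 30 kg/m2); no leisure physical activity is exactly 0 MET h/week;
#' low vegetables inclusive (<= 200 g/day); high red meat strict (> 65 g/day);
#' NSAID/ASA non-use is the risk category.
#'
#' @param alcohol_male,alcohol_female Standard units of alcohol per day.
#' @param bmi kg/m2, inclusive.
#' @param vegetables g/day, inclusive (at or below is the risk category).
#' @param red_meat g/day, strict (above is the risk category).
#' @return A named list of cut-offs.
#' @export
risk_factor_cutoffs <- function(alcohol_male = 4, alcohol_female = 2,
                                bmi = 30, vegetables = 200, red_meat = 65) {
  list(alcohol_male = alcohol_male, alcohol_female = alcohol_female,
       bmi = bmi, vegetables = vegetables, red_meat = red_meat)
}

#' Derive the binary risk-factor profile from raw variables
#'
#' Converts raw lifestyle variables into the 0/1 risk indicators used by the
#' environmental risk score, with the risk category coded 1. Missing raw
#' values propagate as `NA` (impute afterwards with [impute_missing()]).
#' Smoking is derived (`smoker_ever`) but is not part of the ERS; family
#' history (any-degree relative) passes through as a 0/1 flag.
#'
#' @param data A cohort tibble with columns `sex`, `alcohol_sua_day`, `bmi`,
#'   `met_h_week`, `red_meat_g_day`, `vegetables_g_day`, `nsaid_regular_use`,
#'   `smoking_status`, and optionally `family_history`.
#' @param cutoffs A [risk_factor_cutoffs()] list.
#' @return `data` with the indicator columns `alcohol_high`, `obese`,
#'   `no_physical_activity`, `low_vegetables`, `high_red_meat`,
#'   `no_nsaid_asa`, `smoker_ever` appended (overwritten if present).
#' @export
derive_risk_factors <- function(data, cutoffs = risk_factor_cutoffs()) {
  assert_columns(data, c("sex", "alcohol_sua_day", "bmi", "met_h_week",
                         "red_meat_g_day", "vegetables_g_day",
                         "nsaid_regular_use", "smoking_status"),
                 "derive_risk_factors()")
  for (v in c("alcohol_sua_day", "bmi", "met_h_week", "red_meat_g_day",
              "vegetables_g_day")) {
    if (any(data[[v]] < 0, na.rm = TRUE)) {
      abort(sprintf("Negative values in `%s` are not valid.", v))
    }
  }
  if (!all(data$sex %in% c("male", "female"))) {
    abort("`sex` must be \"male\" or \"female\".")
  }
  thr <- ifelse(data$sex == "male", cutoffs$alcohol_male,
                cutoffs$alcohol_female)
  dplyr::mutate(
    data,
    alcohol_high = as.integer(.data$alcohol_sua_day > thr),
    obese = as.integer(.data$bmi >= cutoffs$bmi),
    no_physical_activity = as.integer(.data$met_h_week == 0),
    low_vegetables = as.integer(.data$vegetables_g_day <= cutoffs$vegetables),
    high_red_meat = as.integer(.data$red_meat_g_day > cutoffs$red_meat),
    no_nsaid_asa = as.integer(.data$nsaid_regular_use == 0),
    smoker_ever = as.integer(.data$smoking_status %in% c("former", "current"))
  )
}

#' Deterministic single imputation of missing values
#'
#' Continuous variables are imputed with the expected value from an ordinary
#' least-squares regression on the predictor set fitted to complete cases;
#' categorical and binary variables (including 0/1/2 genotypes) with the
#' modal category among complete cases (ties towards the smallest value).
#' Observed values are never altered; the imputation is deterministic given
#' the cohort.
#'
#' @param data A cohort tibble.
#' @param vars Columns to impute; defaults to every column with missing
#'   values except the design variables (`subject_id`, `case_status`, `age`,
#'   `sex`, `region`).
#' @param predictors Predictor columns of the complete-case regression for
#'   continuous variables (default age, sex, and case status); they must be
#'   complete.
#' @return `data` with no missing values in `vars`.
#' @export
impute_missing <- function(data, vars = NULL,
                           predictors = c("age", "sex", "case_status")) {
  design <- c("subject_id", "case_status", "age", "sex", "region")
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, anyNA, logical(1))]
    vars <- setdiff(vars, design)
  }
  if (!length(vars)) return(data)
  assert_columns(data, vars, "impute_missing()")
  predictors <- intersect(predictors, names(data))
  for (p in predictors) {
    if (anyNA(data[[p]])) {
      abort(sprintf("Imputation predictor `%s` must be complete.", p))
    }
  }
  for (v in vars) {
    miss <- is.na(data[[v]])
    if (!any(miss)) next
    if (all(miss)) {
      abort(sprintf("`%s` is missing for every subject; cannot impute.", v))
    }
    x <- data[[v]]
    # whole-valued variables with <= 3 levels (binary flags, 0/1/2 genotypes)
    # are categorical; everything else numeric is treated as continuous
    categorical <- !is.numeric(x) ||
      (all(x[!miss] == round(x[!miss])) && length(unique(x[!miss])) <= 3)
    if (categorical || !length(predictors)) {
      data[[v]][miss] <- mode_value(x)
    } else {
      df <- data[predictors]
      df$.target <- x
      fit <- lm(.target ~ ., data = df[!miss, , drop = FALSE])
      data[[v]][miss] <- predict(fit, newdata = df[miss, , drop = FALSE])
    }
  }
  data
}
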