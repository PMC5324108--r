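#' Read an age/sex cumulative-incidence table
#'
#' Comma-separated with header `sex,age,cum_risk_per100`: registry-style
#' cumulative risk of disease (per 100 persons) up to each age, one monotone
#' grid per sex.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_incidence_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sex = readr::col_character(),
                           age = readr::col_double(),
                           cum_risk_per100 = readr::col_double()
                         ))
  validate_incidence_table(tab)
}

validate_incidence_table <- function(tab) {
  assert_columns(tab, c("sex", "age", "cum_risk_per100"),
                 "An incidence table")
  if (any(tab$cum_risk_per100 < 0 | tab$cum_risk_per100 > 100)) {
    abort("`cum_risk_per100` must lie in [0, 100].")
  }
  tab <- dplyr::arrange(tab, .data$sex, .data$age)
  bad <- tab |>
    dplyr::group_by(.data$sex) |>
    dplyr::summarise(ok = !is.unsorted(.data$cum_risk_per100), .groups = "drop")
  if (!all(bad$ok)) {
    abort("Cumulative risk must be non-decreasing in age within each sex.")
  }
  tibble::as_tibble(tab)
}

#' Synthetic Spanish-registry-style incidence fixture
#'
#' A packaged synthetic cumulative-incidence table shaped like Spanish
#' registry curves (exponential rise from age 50, male above female, lifetime
#' cumulative risk about 10 per 100 men and 5 per 100 women). It is a
#' constructed stand-in for registry data, not real registry figures.
#'
#' @return An incidence tibble (`sex`, `age`, `cum_risk_per100`).
#' @export
synthetic_incidence_table <- function() {
  read_incidence_table(system.file("extdata", "incidence_spain_synthetic.csv",
                                   package = "crcrisk", mustWork = TRUE))
}

#' Project cumulative risk for a set of relative risk scores
#'
#' Multiplies the baseline cumulative risk by each relative risk score,
#' capping at 100 per 100 (capped values are flagged). `rs = 1` reproduces
#' the input table.
#'
#' @param table An incidence tibble (see [read_incidence_table()]).
#' @param rs_values Positive relative risk scores.
#' @return A tibble of class `crc_projection`: `sex`, `age`, `rs`,
#'   `cum_risk_per100`, `capped`.
#' @export
#' @examples
#' project_cumulative_risk(synthetic_incidence_table(), c(0.5, 1, 2))
project_cumulative_risk <- function(table, rs_values) {
  table <- validate_incidence_table(table)
  assert_positive(rs_values, "rs_values")
  out <- tidyr::crossing(table, rs = sort(unique(rs_values))) |>
    dplyr::mutate(
      raw = .data$cum_risk_per100 * .data$rs,
      capped = .data$raw > 100,
      cum_risk_per100 = pmin(.data$raw, 100)
    ) |>
    dplyr::select("sex", "age", "rs", "cum_risk_per100", "capped") |>
    dplyr::arrange(.data$sex, .data$rs, .data$age)
  class(out) <- c("crc_projection", class(out))
  out
}

#' Risk-advancement period of a relative risk score
#'
#' The number of years earlier at which a subject with relative risk `rs`
#' reaches the cumulative risk of an average-risk subject at
#' `reference_age`: solves `rs * CR(a) = CR(reference_age)` by monotone
#' piecewise-linear interpolation of the incidence curve and returns
#' `reference_age - a`.
#'
#' @param table An incidence tibble.
#' @param rs Positive relative risk score(s).
#' @param reference_age Reference age, within the table's age range.
#' @param sex `"male"`, `"female"`, or both.
#' @return A tibble: `sex`, `rs`, `reference_age`, `equivalent_age`,
#'   `advancement_years` (positive when `rs > 1`).
#' @export
risk_advancement_age <- function(table, rs, reference_age,
                                 sex = c("male", "female")) {
  table <- validate_incidence_table(table)
  assert_positive(rs, "rs")
  sexes <- intersect(sex, unique(table$sex))
  if (!length(sexes)) abort("Requested sex not present in the table.")
  rows <- tidyr::crossing(sex = sexes, rs = rs)
  purrr::pmap(rows, function(sex, rs) {
    tab <- table[table$sex == sex, , drop = FALSE]
    if (nrow(tab) < 2) abort("Need at least two ages per sex.")
    if (reference_age < min(tab$age) || reference_age > max(tab$age)) {
      abort("`reference_age` lies outside the incidence table's age range.")
    }
    cr <- tab$cum_risk_per100
    if (any(diff(cr) <= 0)) {
      abort(paste0("Cumulative risk must be strictly increasing in age to ",
                   "invert the curve for sex ", sex, "."))
    }
    cr_ref <- approx(tab$age, cr, xout = reference_age)$y
    target <- cr_ref / rs
    if (target < min(cr) || target > max(cr)) {
      abort(sprintf(
        "Target cumulative risk %.4g for rs = %.3g is outside the curve's range [%.4g, %.4g].",
        target, rs, min(cr), max(cr)
      ))
    }
    a <- approx(cr, tab$age, xout = target)$y
    tibble::tibble(sex = sex, rs = rs, reference_age = reference_age,
                   equivalent_age = a,
                   advancement_years = reference_age - a)
  }) |>
    dplyr::bind_rows()
}

#' Positive and negative predictive values via Bayes' theorem
#'
#' `PPV = sens * prior / (sens * prior + (100 - spec) * (1 - prior))` and
#' `NPV = spec * (1 - prior) / (spec * (1 - prior) + (100 - sens) * prior)`,
#' with sensitivity/specificity in percent and the prior a proportion.
#' A zero denominator yields `NA` with a `FALSE` defined-flag.
#'
#' @param sensitivity,specificity Percentages in \[0, 100\] (recycled).
#' @param prior Pre-test disease probability in \[0, 1\] (recycled).
#' @return A tibble: inputs plus `ppv`, `npv`, `ppv_defined`, `npv_defined`.
#' @export
#' @examples
#' ppv_npv(41.62, 84.66, 0.03)$ppv # about 0.077
ppv_npv <- function(sensitivity, specificity, prior) {
  if (any(sensitivity < 0 | sensitivity > 100) ||
      any(specificity < 0 | specificity > 100)) {
    abort("Sensitivity and specificity must be percentages in [0, 100].")
  }
  assert_probability(prior, "prior")
  s <- sensitivity / 100
  sp <- specificity / 100
  den_p <- s * prior + (1 - sp) * (1 - prior)
  den_n <- sp * (1 - prior) + (1 - s) * prior
  tibble::tibble(
    sensitivity = sensitivity, specificity = specificity, prior = prior,
    ppv = ifelse(den_p > 0, s * prior / den_p, NA_real_),
    npv = ifelse(den_n > 0, sp * (1 - prior) / den_n, NA_real_),
    ppv_defined = den_p > 0,
    npv_defined = den_n > 0
  )
}

parse_decades <- function(decades) {
  if (is.character(decades)) {
    parts <- strsplit(decades, "-", fixed = TRUE)
    ok <- vapply(parts, length, integer(1)) == 2
    if (!all(ok)) abort("Decades must look like \"40-49\".")
    starts <- as.numeric(vapply(parts, `[[`, character(1), 1))
    ends <- as.numeric(vapply(parts, `[[`, character(1), 2)) + 1
  } else if (is.list(decades)) {
    starts <- vapply(decades, `[[`, numeric(1), 1)
    ends <- vapply(decades, `[[`, numeric(1), 2)
  } else {
    abort("`decades` must be character ranges or a list of (start, end).")
  }
  if (any(ends <= starts)) abort("Decade ends must exceed starts.")
  tibble::tibble(decade = if (is.character(decades)) decades
                 else sprintf("%g-%g", starts, ends),
                 start = starts, end = ends)
}

#' Positive predictive value of the risk model by age range
#'
#' For each age range, the pre-test probability is the cumulative risk of
#' developing disease during the range (the difference of the cumulative
#' risks at its ends, interpolated linearly, converted to a proportion) and
#' the PPV follows from the cut-off's sensitivity/specificity via
#' [ppv_npv()].
#'
#' @param table An incidence tibble.
#' @param perf A [screening_performance()] tibble (columns `cutoff`,
#'   `sensitivity`, `specificity`).
#' @param decades Age ranges as strings such as `"40-49"` (meaning ages 40
#'   up to but excluding 50).
#' @param sex Sexes to project.
#' @return A tibble: `sex`, `decade`, `cutoff`, `sensitivity`,
#'   `specificity`, `prior`, `ppv`.
#' @export
ppv_by_age <- function(table, perf,
                       decades = c("40-49", "50-59", "60-69", "70-79"),
                       sex = c("male", "female")) {
  table <- validate_incidence_table(table)
  assert_columns(perf, c("cutoff", "sensitivity", "specificity"),
                 "ppv_by_age()")
  spans <- parse_decades(decades)
  sexes <- intersect(sex, unique(table$sex))
  if (!length(sexes)) abort("Requested sex not present in the table.")
  grid <- tidyr::crossing(sex = sexes, spans)
  out <- purrr::pmap(grid, function(sex, decade, start, end) {
    tab <- table[table$sex == sex, , drop = FALSE]
    if (start < min(tab$age) || end > max(tab$age)) {
      abort(sprintf("Decade %s lies outside the incidence table for %s.",
                    decade, sex))
    }
    cr <- approx(tab$age, tab$cum_risk_per100, xout = c(start, end))$y
    prior <- (cr[2] - cr[1]) / 100
    res <- ppv_npv(perf$sensitivity, perf$specificity, prior)
    tibble::tibble(sex = sex, decade = decade, cutoff = perf$cutoff,
                   sensitivity = perf$sensitivity,
                   specificity = perf$specificity,
                   prior = prior, ppv = res$ppv)
  })
  dplyr::bind_rows(out)
}
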