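#' Fit the propensity-adjusted multivariate risk model
#'
#' Maximum-likelihood logistic regression of case status on the requested
#' risk terms plus the propensity score as a continuous covariate. Two
#' canonical term sets are the score-level model
#' (`c("ers", "family_history", "grs")`) and the factor-level model (the six
#' binary factors plus `family_history` and `grs`).
#'
#' @param data A cohort tibble with `case_status`, the term columns, and the
#'   propensity column.
#' @param terms Character vector of risk-term column names.
#' @param ps_col Name of the propensity-score column.
#' @return An object of class `crc_risk_fit`; use [tidy()] for odds ratios
#'   with Wald 95% confidence intervals and [glance()] for fit statistics.
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_config(n_cases = 150, n_controls = 300,
#'                                         n_regions = 3), seed = 7) |>
#'   derive_risk_factors() |>
#'   compute_ers() |>
#'   compute_grs() |>
#'   add_propensity()
#' fit <- fit_risk_model(cohort)
#' tidy(fit)
#' }
fit_risk_model <- function(data, terms = c("ers", "family_history", "grs"),
                           ps_col = "ps") {
  assert_columns(data, c("case_status", terms, ps_col), "fit_risk_model()")
  df <- as.data.frame(data[c(terms, ps_col)])
  df$.y <- case_indicator(data$case_status)
  formula <- reformulate(c(terms, ps_col), response = ".y")

  separation <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separation) {
    abort(paste0(
      "Risk model shows complete or quasi-complete separation; ",
      "largest |coefficient| = ",
      format(max(abs(coef(fit)), na.rm = TRUE), digits = 3), "."
    ))
  }
  if (!fit$converged) abort("Risk model did not converge.")
  if (anyNA(coef(fit))) {
    abort(paste0("Risk model design is rank deficient (terms: ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
                 ")."))
  }
  structure(list(glm = fit, terms = terms, ps_col = ps_col,
                 n = nrow(df), n_case = sum(df$.y),
                 n_control = sum(df$.y == 0)),
            class = "crc_risk_fit")
}

#' @export
print.crc_risk_fit <- function(x, ...) {
  cat("<crc_risk_fit> logistic risk model,",
      x$n_case, "cases /", x$n_control, "controls\n")
  print(tidy(x), ...)
  invisible(x)
}

#' @describeIn fit_risk_model Per-term odds ratios with Wald 95% CIs.
#' @param x A `crc_risk_fit`.
#' @param exponentiate Return odds ratios (default) or log-odds coefficients.
#' @param ... Unused.
#' @method tidy crc_risk_fit
#' @export
tidy.crc_risk_fit <- function(x, exponentiate = TRUE, ...) {
  sm <- summary(x$glm)$coefficients
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  z <- stats::qnorm(0.975)
  out <- tibble::tibble(
    term = rownames(sm),
    estimate = if (exponentiate) exp(est) else est,
    std.error = se,
    statistic = sm[, "z value"],
    p.value = sm[, "Pr(>|z|)"],
    conf.low = if (exponentiate) exp(est - z * se) else est - z * se,
    conf.high = if (exponentiate) exp(est + z * se) else est + z * se
  )
  out
}

#' @describeIn fit_risk_model One-row fit summary.
#' @method glance crc_risk_fit
#' @export
glance.crc_risk_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$n, n_case = x$n_case, n_control = x$n_control,
    logLik = as.numeric(logLik(x$glm)),
    AIC = AIC(x$glm),
    deviance = x$glm$deviance,
    df.residual = x$glm$df.residual
  )
}

#' Crude odds ratio from a 2x2 table
#'
#' `OR = (a * d) / (b * c)` with the Woolf logit confidence interval
#' `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. All four counts
#' must be positive (no continuity correction is applied).
#'
#' @param exposed_cases,unexposed_cases,exposed_controls,unexposed_controls
#'   Non-negative integer counts (a, b, c, d).
#' @return A one-row tibble with `or`, `conf.low`, `conf.high`.
#' @export
#' @examples
#' crude_or(649, 80, 1441, 394) # about 2.22
crude_or <- function(exposed_cases, unexposed_cases,
                     exposed_controls, unexposed_controls) {
  counts <- c(a = exposed_cases, b = unexposed_cases,
              c = exposed_controls, d = unexposed_controls)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("Counts must be non-negative whole numbers.")
  }
  if (any(counts == 0)) {
    abort("A zero cell makes the crude odds ratio undefined (no continuity correction).")
  }
  log_or <- log(counts[["a"]]) - log(counts[["b"]]) -
    log(counts[["c"]]) + log(counts[["d"]])
  se <- sqrt(sum(1 / counts))
  ci <- wald_ci_or(log_or, se)
  tibble::tibble(or = exp(log_or), conf.low = ci[1], conf.high = ci[2])
}

#' Likelihood ratios from sensitivity and specificity
#'
#' `PLR = sens / (100 - spec)` and `NLR = (100 - sens) / spec`, with
#' sensitivity and specificity on the percentage scale. Degenerate
#' denominators give `Inf` together with a `FALSE` defined-flag.
#'
#' @param sensitivity,specificity Percentages in \[0, 100\].
#' @return A tibble with `positive_lr`, `negative_lr` and defined-flags.
#' @export
#' @examples
#' likelihood_ratios(41.62, 84.66) # PLR about 2.71
likelihood_ratios <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 100) ||
      any(specificity < 0 | specificity > 100)) {
    abort("Sensitivity and specificity must be percentages in [0, 100].")
  }
  plr_def <- specificity < 100
  nlr_def <- specificity > 0
  tibble::tibble(
    sensitivity = sensitivity,
    specificity = specificity,
    positive_lr = ifelse(plr_def, sensitivity / (100 - specificity), Inf),
    negative_lr = ifelse(nlr_def, (100 - sensitivity) / specificity, Inf),
    positive_lr_defined = plr_def,
    negative_lr_defined = nlr_def
  )
}
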