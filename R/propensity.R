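#' Fit the propensity model of the frequency-matched design
#'
#' Logistic regression of case status on age, sex, education, recruiting
#' centre (region), the first three ancestry components, and the age x sex
#' and centre x sex interactions. The per-subject prediction on the logit
#' scale is the propensity score, carried as a continuous adjustment
#' covariate by every risk model. Factors with a single observed level (e.g.
#' a single-centre cohort) are absorbed into the intercept, and collinear
#' columns are dropped with a warning; complete separation is an error.
#'
#' @param data A cohort tibble with `case_status`, `age`, `sex`, `education`,
#'   `region`, `pc1`, `pc2`, `pc3`.
#' @param age `"continuous"` (default) enters age as a linear term;
#'   `"bands"` as 5-year band indicators.
#' @param age_band_width Band width in years when `age = "bands"`.
#' @return An object of class `crc_propensity` with the fitted coefficients
#'   and the training linear predictors (`$lp`).
#' @export
fit_propensity <- function(data, age = c("continuous", "bands"),
                           age_band_width = 5) {
  age_mode <- match.arg(age)
  assert_columns(data, c("case_status", "age", "sex", "education", "region",
                         "pc1", "pc2", "pc3"), "fit_propensity()")
  df <- propensity_frame(data, age_mode, age_band_width)
  df$.y <- case_indicator(data$case_status)

  multi <- function(v) is.numeric(df[[v]]) || nlevels(df[[v]]) >= 2
  rhs <- c(if (multi(".age")) ".age", "pc1", "pc2", "pc3")
  has_sex <- multi(".sex")
  if (has_sex) rhs <- c(rhs, ".sex")
  if (multi(".education")) rhs <- c(rhs, ".education")
  has_region <- multi(".region")
  if (has_region) rhs <- c(rhs, ".region")
  if (has_sex && multi(".age")) rhs <- c(rhs, ".age:.sex")
  if (has_sex && has_region) rhs <- c(rhs, ".region:.sex")
  formula <- reformulate(rhs, response = ".y")

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
  if (separation || !fit$converged) {
    abort("Propensity model did not converge (possible complete separation).")
  }
  beta <- coef(fit)
  dropped <- names(beta)[is.na(beta)]
  if (length(dropped)) {
    warn(paste0("Dropping collinear propensity terms: ",
                paste(dropped, collapse = ", "), "."))
    beta[is.na(beta)] <- 0
  }
  mm <- model.matrix(fit)
  structure(list(
    formula = formula,
    coefficients = beta,
    terms = delete.response(terms(fit)),
    xlevels = fit$xlevels,
    contrasts = fit$contrasts,
    age_mode = age_mode,
    age_band_width = age_band_width,
    lp = as.numeric(mm %*% beta),
    n = nrow(df),
    case_fraction = mean(df$.y),
    glm = fit
  ), class = "crc_propensity")
}

propensity_frame <- function(data, age_mode, age_band_width) {
  tibble::tibble(
    .age = if (age_mode == "continuous") as.numeric(data$age)
           else factor(age_band(data$age, age_band_width)),
    .sex = factor(data$sex),
    .education = factor(data$education),
    .region = factor(data$region),
    pc1 = data$pc1, pc2 = data$pc2, pc3 = data$pc3
  )
}

#' Attach the propensity score to a cohort
#'
#' Computes logit-scale predictions from a [fit_propensity()] fit and appends
#' them as a `ps` column. A factor level unseen at fitting time (a new
#' centre or education level) is an error.
#'
#' @param data A cohort tibble with the propensity design columns.
#' @param fit A `crc_propensity` object.
#' @param ps_col Name of the column to create.
#' @return `data` with the propensity column appended.
#' @export
attach_propensity <- function(data, fit, ps_col = "ps") {
  if (!inherits(fit, "crc_propensity")) {
    abort("`fit` must come from fit_propensity().")
  }
  df <- propensity_frame(data, fit$age_mode, fit$age_band_width)
  mm <- tryCatch(
    {
      mf <- model.frame(fit$terms, df, xlev = fit$xlevels)
      model.matrix(fit$terms, mf, contrasts.arg = fit$contrasts)
    },
    error = function(e) {
      abort(paste0("Cannot score cohort with this propensity fit ",
                   "(unseen factor level?): ", conditionMessage(e)))
    }
  )
  data[[ps_col]] <- as.numeric(mm %*% fit$coefficients[colnames(mm)])
  data
}

#' Fit the propensity model and attach the score in one step
#'
#' @inheritParams fit_propensity
#' @param ps_col Name of the propensity column.
#' @return `data` with the propensity column appended.
#' @export
add_propensity <- function(data, age = c("continuous", "bands"),
                           ps_col = "ps") {
  fit <- fit_propensity(data, age = age)
  data[[ps_col]] <- fit$lp
  data
}

#' @export
print.crc_propensity <- function(x, ...) {
  cat("<crc_propensity>\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d subjects, case fraction %.3f, %d coefficients\n",
              x$n, x$case_fraction, length(x$coefficients)))
  invisible(x)
}

#' @describeIn fit_propensity Coefficients of the propensity model as a tibble.
#' @param x A `crc_propensity` object.
#' @param ... Unused.
#' @method tidy crc_propensity
#' @export
tidy.crc_propensity <- function(x, ...) {
  sm <- summary(x$glm)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "z value"],
    p.value = sm[, "Pr(>|z|)"]
  )
}

#' @describeIn fit_propensity One-row model summary.
#' @method glance crc_propensity
#' @export
glance.crc_propensity <- function(x, ...) {
  tibble::tibble(
    nobs = x$n,
    case_fraction = x$case_fraction,
    logLik = as.numeric(logLik(x$glm)),
    AIC = AIC(x$glm),
    deviance = x$glm$deviance
  )
}
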