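# Internal validators and small shared helpers.

assert_probability <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1].", name))
  }
  invisible(x)
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    abort(sprintf("`%s` must be a positive number.", name))
  }
  invisible(x)
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != round(x)) {
    abort(sprintf("`%s` must be a positive whole number.", name))
  }
  invisible(as.integer(x))
}

assert_columns <- function(data, cols, context) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf(
      "%s requires column%s %s, not found in `data`.",
      context, if (length(missing) > 1) "s" else "",
      paste0("`", missing, "`", collapse = ", ")
    ))
  }
  invisible(data)
}

# Convert a case/control label column (character/factor "case"/"control" or
# a 0/1 numeric) to a 0/1 integer indicator with 1 = case.
case_indicator <- function(x) {
  if (is.numeric(x)) {
    if (anyNA(x) || !all(x %in% c(0, 1))) {
      abort("Numeric case labels must be 0 (control) or 1 (case).")
    }
    return(as.integer(x))
  }
  x <- as.character(x)
  bad <- setdiff(unique(x), c("case", "control"))
  if (anyNA(x) || length(bad)) {
    abort("Case labels must be \"case\" or \"control\" (or a 0/1 indicator).")
  }
  as.integer(x == "case")
}

# Start of the 5-year (by default) age band containing each age.
age_band <- function(age, width = 5) width * floor(age / width)

# Modal value; ties broken towards the smallest value so imputation is
# deterministic.
mode_value <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) abort("Cannot take the mode of an all-missing vector.")
  ux <- sort(unique(x))
  ux[which.max(tabulate(match(x, ux)))]
}

wald_ci_or <- function(estimate, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(exp(estimate - z * se), exp(estimate + z * se))
}
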