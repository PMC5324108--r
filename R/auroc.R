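#' Area under the ROC curve by rank concordance
#'
#' Mann-Whitney form: the probability that a randomly chosen case scores
#' higher than a randomly chosen control, ties counting one half.
#'
#' @param score Numeric risk scores.
#' @param label Case/control labels (`"case"`/`"control"` or 0/1).
#' @return The AUROC as a single number in \[0, 1\].
#' @export
auroc <- function(score, label) {
  y <- case_indicator(label)
  if (length(score) != length(y)) abort("`score` and `label` lengths differ.")
  if (anyNA(score)) abort("`score` must not contain missing values.")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    abort("AUROC needs at least one case and one control.")
  }
  r <- rank(score, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Propensity-stratified, case-weighted AUROC
#'
#' Subjects are split into quantile strata of the propensity score over the
#' pooled sample (ties at a boundary fall into the lower stratum). The AUROC
#' is computed within each stratum by rank concordance and averaged with
#' weights proportional to the number of cases per stratum. A stratum with
#' no cases gets weight zero (with a warning); a stratum with cases but no
#' controls is an error. With `n_strata = 1` this reduces to the plain
#' pooled AUROC.
#'
#' @param data A tibble containing the score, label and propensity columns.
#' @param score,label,ps Columns (tidy-eval) holding the risk score, the
#'   case/control label and the propensity score.
#' @param n_strata Number of propensity strata (default 5, quintiles).
#' @return A one-row tibble: `method`, `estimate`, `conf.low`, `conf.high`
#'   (both `NA` here; see [cv_auroc()] for bootstrap intervals), `n_strata`.
#' @export
ps_stratified_auroc <- function(data, score, label = case_status, ps = ps,
                                n_strata = 5) {
  n_strata <- assert_count(n_strata, "n_strata")
  s <- dplyr::pull(data, {{ score }})
  y <- case_indicator(dplyr::pull(data, {{ label }}))
  psv <- dplyr::pull(data, {{ ps }})
  if (anyNA(psv)) abort("Propensity scores must not be missing.")

  breaks <- quantile(psv, probs = seq(0, 1, length.out = n_strata + 1),
                     names = FALSE)
  ub <- unique(breaks)
  if (length(ub) < length(breaks)) {
    warn("Tied propensity quantiles; collapsing duplicated strata.")
  }
  stratum <- if (length(ub) > 2) {
    cut(psv, breaks = ub, include.lowest = TRUE, right = TRUE)
  } else {
    factor(rep(1, length(psv)))
  }

  per <- lapply(levels(stratum), function(lv) {
    idx <- stratum == lv
    n_case <- sum(y[idx] == 1)
    n_control <- sum(y[idx] == 0)
    if (n_case > 0 && n_control == 0) {
      abort(sprintf("Propensity stratum %s has cases but no controls.", lv))
    }
    if (n_case == 0) {
      warn(sprintf("Propensity stratum %s has no cases; weight 0.", lv))
      return(c(auc = NA_real_, w = 0))
    }
    c(auc = auroc(s[idx], y[idx]), w = n_case)
  })
  aucs <- vapply(per, `[[`, numeric(1), "auc")
  w <- vapply(per, `[[`, numeric(1), "w")
  estimate <- sum(aucs[w > 0] * w[w > 0]) / sum(w)
  tibble::tibble(
    method = if (length(ub) > 2) "ps_stratified" else "plain",
    estimate = estimate,
    conf.low = NA_real_, conf.high = NA_real_,
    n_strata = nlevels(stratum)
  )
}

risk_model_formula <- function(terms, ps_col) {
  reformulate(c(terms, ps_col), response = ".y")
}

cv_heldout_scores <- function(data, terms, ps_col, k) {
  y <- case_indicator(data$case_status)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 < k) abort("Too few cases to give every fold a case.")
  if (n0 < k) abort("Too few controls to give every fold a control.")
  fold <- integer(length(y))
  fold[y == 1] <- sample(rep_len(seq_len(k), n1))
  fold[y == 0] <- sample(rep_len(seq_len(k), n0))
  df <- as.data.frame(data[c(terms, ps_col)])
  df$.y <- y
  formula <- risk_model_formula(terms, ps_col)
  scores <- numeric(length(y))
  for (i in seq_len(k)) {
    fit <- suppressWarnings(
      glm(formula, data = df[fold != i, , drop = FALSE], family = binomial())
    )
    scores[fold == i] <- predict(fit, newdata = df[fold == i, , drop = FALSE])
  }
  tibble::tibble(.score = scores, .y = y, .ps = data[[ps_col]])
}

#' Cross-validated, propensity-stratified AUROC with bootstrap CI
#'
#' K-fold cross-validation with folds stratified by case status: the risk
#' model is refit on k-1 folds and held-out subjects are scored by the
#' fitted linear predictor. The pooled held-out scores are then fed to
#' [ps_stratified_auroc()]. The confidence interval is a percentile
#' bootstrap over subject-level resamples, repeating the whole
#' cross-validation (with re-randomized folds) per resample.
#'
#' @param data A cohort tibble with `case_status`, the model terms and the
#'   propensity column.
#' @param terms Risk-model term columns.
#' @param k Number of folds.
#' @param n_boot Bootstrap resamples for the 95% CI (0 skips the interval).
#' @param n_strata Propensity strata for the stratified AUROC.
#' @param ps_col Propensity-score column name.
#' @param seed Optional integer seed.
#' @return A one-row tibble: `method`, `estimate`, `conf.low`, `conf.high`,
#'   `k`, `n_boot`.
#' @export
cv_auroc <- function(data, terms = c("ers", "family_history", "grs"),
                     k = 5, n_boot = 200, n_strata = 5, ps_col = "ps",
                     seed = NULL) {
  if (k < 2) abort("`k` must be at least 2.")
  assert_columns(data, c("case_status", terms, ps_col), "cv_auroc()")
  if (!is.null(seed)) set.seed(seed)
  run_once <- function(d) {
    held <- cv_heldout_scores(d, terms, ps_col, k)
    ps_stratified_auroc(held, score = .data$.score, label = .data$.y,
                        ps = .data$.ps, n_strata = n_strata)$estimate
  }
  estimate <- run_once(data)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(data), replace = TRUE)
      run_once(data[idx, , drop = FALSE])
    }, numeric(1))
    ci <- unname(quantile(boots, c(0.025, 0.975)))
  }
  tibble::tibble(method = "cv_ps_stratified", estimate = estimate,
                 conf.low = ci[1], conf.high = ci[2],
                 k = k, n_boot = n_boot)
}

#' Apparent (resubstitution) stratified AUROC of a risk model
#'
#' Fits the model on the full cohort and evaluates the stratified AUROC on
#' the same subjects; the optimistic counterpart of [cv_auroc()].
#'
#' @inheritParams cv_auroc
#' @return A one-row tibble as in [ps_stratified_auroc()].
#' @export
apparent_auroc <- function(data, terms = c("ers", "family_history", "grs"),
                           n_strata = 5, ps_col = "ps") {
  assert_columns(data, c("case_status", terms, ps_col), "apparent_auroc()")
  fit <- fit_risk_model(data, terms = terms, ps_col = ps_col)
  held <- tibble::tibble(
    .score = predict(fit$glm),
    .y = case_indicator(data$case_status),
    .ps = data[[ps_col]]
  )
  out <- ps_stratified_auroc(held, score = .data$.score, label = .data$.y,
                             ps = .data$.ps, n_strata = n_strata)
  out$method <- "apparent_ps_stratified"
  out
}

#' Individual and cumulative AUROC contribution of model variables
#'
#' Computes the cross-validated stratified AUROC of each variable alone,
#' sorts the variables by increasing individual AUROC, and refits the model
#' adding one variable at a time in that order.
#'
#' @inheritParams cv_auroc
#' @param vars Variables to sequence (e.g. the six environmental factors,
#'   then family history, then the GRS).
#' @return A tibble with one row per step: `variable`, `individual_auroc`,
#'   `cumulative_auroc`.
#' @export
cumulative_auroc_curve <- function(data, vars, k = 5, n_strata = 5,
                                   ps_col = "ps", seed = NULL) {
  if (!length(vars)) abort("`vars` must name at least one variable.")
  assert_columns(data, c("case_status", vars, ps_col),
                 "cumulative_auroc_curve()")
  if (!is.null(seed)) set.seed(seed)
  # one fold seed for every refit so the steps differ only by the model terms
  fold_seed <- sample.int(.Machine$integer.max - 1, 1)
  individual <- vapply(vars, function(v) {
    cv_auroc(data, terms = v, k = k, n_boot = 0, n_strata = n_strata,
             ps_col = ps_col, seed = fold_seed)$estimate
  }, numeric(1))
  ord <- order(individual)
  vars <- vars[ord]
  individual <- individual[ord]
  cumulative <- vapply(seq_along(vars), function(i) {
    cv_auroc(data, terms = vars[seq_len(i)], k = k, n_boot = 0,
             n_strata = n_strata, ps_col = ps_col, seed = fold_seed)$estimate
  }, numeric(1))
  tibble::tibble(variable = vars, individual_auroc = unname(individual),
                 cumulative_auroc = cumulative)
}

#' Screening performance of the risk score at chosen cut-offs
#'
#' A subject is test-positive when the risk score is at or above the
#' cut-off. Sensitivity is the percentage of cases testing positive,
#' specificity the percentage of controls testing negative; likelihood
#' ratios follow via [likelihood_ratios()].
#'
#' @param data A tibble with the risk-score and label columns.
#' @param cutoffs Numeric vector of risk-score cut-offs.
#' @param rs_col Name of the risk-score column.
#' @param label_col Name of the case/control label column.
#' @return A tibble with one row per cut-off: `cutoff`, `sensitivity`,
#'   `specificity`, `positive_lr`, `negative_lr` and defined-flags.
#' @export
screening_performance <- function(data, cutoffs, rs_col = "rs",
                                  label_col = "case_status") {
  assert_columns(data, c(rs_col, label_col), "screening_performance()")
  if (!is.numeric(cutoffs) || !all(is.finite(cutoffs))) {
    abort("`cutoffs` must be finite numbers.")
  }
  rs <- data[[rs_col]]
  y <- case_indicator(data[[label_col]])
  if (!any(y == 1) || !any(y == 0)) {
    abort("Both cases and controls are required.")
  }
  rows <- purrr::map(sort(cutoffs), function(ct) {
    sens <- 100 * mean(rs[y == 1] >= ct)
    spec <- 100 * mean(rs[y == 0] < ct)
    dplyr::bind_cols(tibble::tibble(cutoff = ct),
                     likelihood_ratios(sens, spec))
  })
  dplyr::bind_rows(rows)
}
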