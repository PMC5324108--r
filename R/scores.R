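#' Odds-ratio parameters of the relative risk score
#'
#' The relative risk score is
#' `RS = OR_E^(ERS - e_ref) * OR_F^FH * OR_G^(GRS - g_ref)`,
#' equal to 1 for the reference profile (the population-average number of
#' environmental risk factors and risk alleles, no family history). Defaults
#' are the fitted multivariate odds ratios 1.36 / 2.25 / 1.07 with reference
#' values 3 factors and 22 alleles.
#'
#' @param or_per_factor,or_fh,or_per_allele Positive odds ratios.
#' @param ers_reference,grs_reference Reference (population-average) ERS and
#'   GRS.
#' @return A named list of class `risk_score_params`.
#' @export
risk_score_params <- function(or_per_factor = 1.36, or_fh = 2.25,
                              or_per_allele = 1.07, ers_reference = 3,
                              grs_reference = 22) {
  assert_positive(or_per_factor, "or_per_factor")
  assert_positive(or_fh, "or_fh")
  assert_positive(or_per_allele, "or_per_allele")
  if (!is.finite(ers_reference) || !is.finite(grs_reference)) {
    abort("Reference scores must be finite.")
  }
  structure(list(or_per_factor = or_per_factor, or_fh = or_fh,
                 or_per_allele = or_per_allele,
                 ers_reference = ers_reference,
                 grs_reference = grs_reference),
            class = "risk_score_params")
}

#' Per-SNP weights for the genetic risk score
#'
#' @param values Numeric vector of log-odds weights, one per panel variant
#'   (optionally named by rsid).
#' @param source One of `"unweighted"`, `"published"`, `"refitted"`.
#' @return An object of class `grs_weights`.
#' @export
grs_weights <- function(values, source = c("refitted", "unweighted",
                                           "published")) {
  source <- match.arg(source)
  if (!is.numeric(values) || !all(is.finite(values))) {
    abort("GRS weights must be finite numbers.")
  }
  structure(list(values = values, source = source), class = "grs_weights")
}

resolve_grs_weights <- function(weights, panel) {
  if (inherits(weights, "grs_weights")) {
    w <- weights$values
    if (!is.null(names(w))) {
      missing <- setdiff(panel$rsid, names(w))
      if (length(missing)) {
        abort(paste0("GRS weights missing for: ",
                     paste(missing, collapse = ", "), "."))
      }
      w <- w[panel$rsid]
    }
    if (length(w) != nrow(panel)) {
      abort("GRS weights must have one value per panel variant.")
    }
    return(unname(w))
  }
  if (is.numeric(weights)) {
    return(resolve_grs_weights(grs_weights(weights), panel))
  }
  switch(match.arg(weights, c("unweighted", "published")),
         unweighted = rep(1, nrow(panel)),
         published = log(panel$published_or))
}

#' Compute the genetic risk score
#'
#' Autosomal genotypes count 0/1/2 copies of the risk allele; the X-linked
#' variant is coded 0/0.5/1 (males, hemizygous 0/1, are coded 0/0.5 so both
#' sexes contribute on the same scale). The unweighted GRS is the coded
#' allele count across the panel; weighted variants take the inner product of
#' coded genotypes with per-SNP log-odds weights.
#'
#' @param data A cohort tibble with genotype columns named by panel rsid
#'   (no missing genotypes; impute or drop upstream).
#' @param panel A [snp_panel()].
#' @param weights `"unweighted"` (default), `"published"` (log of the panel's
#'   published ORs), a numeric vector, or a [grs_weights()] object.
#' @return `data` with a `grs` column appended.
#' @export
#' @examples
#' panel <- default_snp_panel()
#' g <- simulate_genotypes(panel, 5, rep("female", 5), seed = 1)
#' compute_grs(g, panel)$grs
compute_grs <- function(data, panel = default_snp_panel(),
                        weights = "unweighted") {
  panel <- snp_panel(panel)
  assert_columns(data, panel$rsid, "compute_grs()")
  geno <- as.matrix(data[panel$rsid])
  if (anyNA(geno)) {
    abort("Genotypes contain missing values; impute or drop them upstream.")
  }
  if (!all(geno %in% c(0, 1, 2))) {
    abort("Genotypes must be allele counts in {0, 1, 2}.")
  }
  coded <- geno
  xcol <- which(is_x_linked(panel))
  if (length(xcol)) coded[, xcol] <- coded[, xcol] / 2
  w <- resolve_grs_weights(weights, panel)
  data$grs <- as.numeric(coded %*% w)
  data
}

#' Refit GRS weights on the data at hand
#'
#' Fits a propensity-adjusted multivariable logistic regression of case
#' status on all coded genotypes jointly and returns the per-SNP
#' coefficients as weights.
#'
#' @inheritParams compute_grs
#' @param ps_col Name of the propensity-score column.
#' @return A [grs_weights()] object with `source = "refitted"`.
#' @export
refit_grs_weights <- function(data, panel = default_snp_panel(),
                              ps_col = "ps") {
  panel <- snp_panel(panel)
  assert_columns(data, c(panel$rsid, "case_status", ps_col),
                 "refit_grs_weights()")
  coded <- as.matrix(data[panel$rsid])
  xcol <- which(is_x_linked(panel))
  if (length(xcol)) coded[, xcol] <- coded[, xcol] / 2
  df <- as.data.frame(coded)
  names(df) <- panel$rsid
  df$.y <- case_indicator(data$case_status)
  df$.ps <- data[[ps_col]]
  fit <- glm(.y ~ ., data = df, family = binomial())
  w <- coef(fit)[panel$rsid]
  grs_weights(w, source = "refitted")
}

#' Compute the environmental risk score
#'
#' The count (0-6) of the six modifiable binary risk factors equal to 1.
#' Family history and smoking are excluded. Requires complete indicators
#' (run [impute_missing()] first when needed).
#'
#' @param data A cohort tibble with the six indicator columns (see
#'   [derive_risk_factors()]).
#' @return `data` with an `ers` column appended.
#' @export
compute_ers <- function(data) {
  factors <- c("alcohol_high", "obese", "no_physical_activity",
               "low_vegetables", "high_red_meat", "no_nsaid_asa")
  assert_columns(data, factors, "compute_ers()")
  mat <- as.matrix(data[factors])
  if (anyNA(mat)) {
    abort("Risk-factor indicators contain missing values; impute first.")
  }
  if (!all(mat %in% c(0, 1))) {
    abort("Risk-factor indicators must be 0/1.")
  }
  data$ers <- as.integer(rowSums(mat))
  data
}

#' Compute the multiplicative relative risk score
#'
#' `RS = OR_E^(ERS - e_ref) * OR_F^FH * OR_G^(GRS - g_ref)`; the reference
#' profile scores exactly 1.
#'
#' @param data A tibble with columns `ers`, `family_history`, `grs`.
#' @param params A [risk_score_params()] list.
#' @return `data` with an `rs` column appended.
#' @export
#' @examples
#' compute_rs(tibble::tibble(ers = 3, family_history = 0, grs = 22))$rs # 1
compute_rs <- function(data, params = risk_score_params()) {
  assert_columns(data, c("ers", "family_history", "grs"), "compute_rs()")
  vals <- c(data$ers, data$family_history, data$grs)
  if (anyNA(vals) || !all(is.finite(vals))) {
    abort("`ers`, `family_history` and `grs` must be finite and non-missing.")
  }
  if (!all(data$family_history %in% c(0, 1))) {
    abort("`family_history` must be 0/1.")
  }
  data$rs <- params$or_per_factor^(data$ers - params$ers_reference) *
    params$or_fh^data$family_history *
    params$or_per_allele^(data$grs - params$grs_reference)
  data
}

#' Append ERS, GRS and RS columns in one step
#'
#' @inheritParams compute_grs
#' @inheritParams compute_rs
#' @return `data` with `ers`, `grs` and `rs` columns.
#' @export
score_cohort <- function(data, panel = default_snp_panel(),
                         params = risk_score_params(),
                         weights = "unweighted") {
  data |>
    compute_ers() |>
    compute_grs(panel = panel, weights = weights) |>
    compute_rs(params = params)
}

#' Odds ratio contrasting high- versus low-GRS groups
#'
#' Propensity-adjusted logistic odds ratio comparing subjects with
#' `grs >= high_cut` against subjects with `grs <= low_cut` (e.g. top versus
#' bottom quintile of the allele count).
#'
#' @param data A cohort tibble with `case_status`, `grs` and the propensity
#'   column.
#' @param low_cut,high_cut Allele-count cuts defining the two groups.
#' @param ps_col Name of the propensity-score column.
#' @return A one-row tibble with `or`, `conf.low`, `conf.high`, group sizes.
#' @export
grs_group_contrast <- function(data, low_cut = 18, high_cut = 26,
                               ps_col = "ps") {
  assert_columns(data, c("case_status", "grs", ps_col),
                 "grs_group_contrast()")
  if (low_cut >= high_cut) abort("`low_cut` must be below `high_cut`.")
  sub <- data[data$grs <= low_cut | data$grs >= high_cut, , drop = FALSE]
  sub$.high <- as.integer(sub$grs >= high_cut)
  y <- case_indicator(sub$case_status)
  counts <- table(group = sub$.high, case = y)
  if (!identical(dim(counts), c(2L, 2L)) || any(counts == 0)) {
    abort("Both GRS groups must contain cases and controls.")
  }
  df <- data.frame(.y = y, .high = sub$.high, .ps = sub[[ps_col]])
  fit <- glm(.y ~ .high + .ps, data = df, family = binomial())
  est <- coef(fit)[[".high"]]
  se <- sqrt(diag(vcov(fit)))[[".high"]]
  ci <- wald_ci_or(est, se)
  tibble::tibble(or = exp(est), conf.low = ci[1], conf.high = ci[2],
                 n_low = sum(sub$.high == 0), n_high = sum(sub$.high == 1))
}
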