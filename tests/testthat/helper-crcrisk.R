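# Shared fixtures built in code.

# A 3-SNP panel (two autosomal, one X-linked) for fast unit tests.
tiny_panel <- function(raf = c(0.3, 0.5, 0.4)) {
  snp_panel(tibble::tibble(
    rsid = c("rsA1", "rsA2", "rsX1"),
    chromosome = c("1", "2", "X"),
    risk_allele = c("A", "C", "G"),
    raf = raf,
    published_or = c(1.10, 1.20, 1.05)
  ))
}

# A scaled-down generator configuration for fast cohort tests.
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_cases = 150, n_controls = 300, n_regions = 3, pool_factor = 4),
    list(...)
  )
  do.call(cohort_config, args)
}

# Full pipeline: simulate, derive indicators, score, attach propensity.
make_scored_cohort <- function(config = small_config(), seed = 1) {
  simulate_cohort(config, seed = seed) |>
    derive_risk_factors() |>
    compute_ers() |>
    compute_grs() |>
    compute_rs() |>
    add_propensity()
}

# Independent AUROC oracle: brute-force all-pairs concordance, ties 1/2.
auroc_pairs <- function(score, label) {
  y <- if (is.numeric(label)) label else as.integer(label == "case")
  cs <- score[y == 1]
  ct <- score[y == 0]
  mean(outer(cs, ct, ">") + 0.5 * outer(cs, ct, "=="))
}

# A cohort with scores unrelated to the outcome (null discrimination).
null_cohort <- function(n_case, n_control, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  tibble::tibble(
    case_status = rep(c("case", "control"), c(n_case, n_control)),
    score = rnorm(n),
    ps = rnorm(n)
  )
}
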