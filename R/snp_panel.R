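#' SNP susceptibility panel
#'
#' A SNP panel is a tibble with one row per susceptibility variant and columns
#' `rsid`, `chromosome`, `risk_allele`, `raf` (risk-allele frequency) and
#' `published_or` (per-allele odds ratio reported by the discovery GWAS).
#' The packaged default is a 21-SNP colorectal-cancer panel with a single
#' X-linked variant (rs5934683); that variant is coded 0/0.5/1 in the genetic
#' risk score while autosomal variants count 0/1/2 risk alleles.
#'
#' @param data A data frame with columns `rsid`, `chromosome`, `risk_allele`,
#'   `raf`, `published_or`.
#' @return A validated tibble of class `snp_panel`.
#' @export
#' @examples
#' panel <- default_snp_panel()
#' nrow(panel) # 21
snp_panel <- function(data) {
  assert_columns(
    data, c("rsid", "chromosome", "risk_allele", "raf", "published_or"),
    "A SNP panel"
  )
  panel <- tibble::as_tibble(data)
  panel$chromosome <- as.character(panel$chromosome)
  if (nrow(panel) < 1) abort("A SNP panel needs at least one variant.")
  if (anyDuplicated(panel$rsid)) {
    abort("`rsid` must be unique within a SNP panel.")
  }
  assert_probability(panel$raf, "raf")
  assert_positive(panel$published_or, "published_or")
  if (sum(panel$chromosome == "X") > 1) {
    abort("At most one panel variant may be X-linked.")
  }
  if (!all(nchar(panel$risk_allele) == 1)) {
    abort("`risk_allele` must be single bases (A/C/G/T).")
  }
  class(panel) <- c("snp_panel", class(panel))
  panel
}

#' Read a SNP panel from a tab-separated file
#'
#' Expects a header line `rsid  chromosome  risk_allele  raf  published_or`.
#'
#' @param path Path to a TSV file.
#' @return A validated `snp_panel` tibble.
#' @export
read_snp_panel <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           rsid = readr::col_character(),
                           chromosome = readr::col_character(),
                           risk_allele = readr::col_character(),
                           raf = readr::col_double(),
                           published_or = readr::col_double()
                         ))
  snp_panel(raw)
}

#' The packaged 21-SNP colorectal-cancer panel
#'
#' @return A `snp_panel` tibble with 21 rows (20 autosomal, rs5934683 on X).
#' @export
default_snp_panel <- function() {
  read_snp_panel(system.file("extdata", "snp_panel_21.tsv",
                             package = "crcrisk", mustWork = TRUE))
}

is_x_linked <- function(panel) panel$chromosome == "X"
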