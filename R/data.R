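#' Published parent-of-origin associations
#'
#' Significant and suggestive POE associations reported by a biobank-scale
#' POE study, transcribed with their parent-specific effect sizes, standard
#' errors and P values, differential P value, trait, locus, discovery scan
#' (`I` imprinted-region focus, `A` additively associated regions, `G`
#' genome-wide) and reported POE class (`B` bipolar, `M` maternal, `P`
#' paternal, `PA` paternal asymmetric). Useful as a reclassification
#' benchmark for [classify_poe()] and as input for [differential_z()].
#'
#' @return A tibble with one row per reported variant-trait association.
#' @examples
#' poe <- published_poe()
#' table(classify_poe(poe$beta_pat / poe$se_pat, poe$beta_mat / poe$se_mat))
#' @export
published_poe <- function() {
  readr::read_tsv(
    system.file("extdata", "published_poe_associations.tsv",
                package = "pofokit"),
    show_col_types = FALSE,
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_double(),
      conditional = readr::col_logical(),
      .default = readr::col_guess()))
}
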