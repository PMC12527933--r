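#' Combine parent-of-origin predictors into one call per target
#'
#' A target can carry several haplotype-0 parent predictions: from genotyped
#' parents (`PED`), X-chromosome sharing (`X`), the sibling crossover score
#' (`SIB`) and mtDNA minor-variant sharing (`MT`). Parental-genome calls
#' override everything; otherwise the predictor with the highest estimated
#' accuracy (probability) wins; residual ties with conflicting sides are
#' broken by overall predictor accuracy, in the order X, SIB, MT.
#' Conflicting mtDNA calls from different 3rd/4th-degree relatives of the
#' same cluster leave the target undetermined.
#'
#' @param predictions Tibble with columns `target`, `predictor` (`"PED"`,
#'   `"X"`, `"SIB"`, `"MT"`), `parent_h0` (`"pat"`/`"mat"`: the parent
#'   assigned to haplotype index 0), `prob`, and optionally `degree`.
#' @param high_conf Probability at or above which a call is flagged high
#'   confidence (default 0.99).
#' @return One row per target: `target`, `parent_h0`, `p_t`, `predictor`,
#'   `determined`, `high_confidence`. Undetermined targets keep `NA` calls.
#' @export
combine_predictors <- function(predictions, high_conf = 0.99) {
  stopifnot(all(c("target", "predictor", "parent_h0", "prob") %in%
                  names(predictions)))
  if (!"degree" %in% names(predictions)) predictions$degree <- NA_integer_
  prio <- c(PED = 0, X = 1, SIB = 2, MT = 3)
  predictions |>
    dplyr::filter(!is.na(.data$prob), !is.na(.data$parent_h0)) |>
    dplyr::group_by(target = .data$target) |>
    dplyr::group_modify(function(d, key) {
      und <- tibble::tibble(parent_h0 = NA_character_, p_t = NA_real_,
                            predictor = NA_character_, determined = FALSE)
      if (any(d$predictor == "PED")) {
        b <- d[d$predictor == "PED", ][1, ]
        return(tibble::tibble(parent_h0 = b$parent_h0, p_t = b$prob,
                              predictor = "PED", determined = TRUE))
      }
      best <- d[d$prob == max(d$prob), ]
      if (length(unique(best$parent_h0)) > 1) {
        best <- best[order(prio[best$predictor]), ]
        top <- best[best$predictor == best$predictor[1], ]
        if (length(unique(top$parent_h0)) > 1) {
          # within-predictor conflict (e.g. mtDNA calls from different
          # distant relatives in one cluster): undetermined
          return(und)
        }
        best <- top
      }
      b <- best[1, ]
      tibble::tibble(parent_h0 = b$parent_h0, p_t = b$prob,
                     predictor = b$predictor, determined = TRUE)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(high_confidence = .data$determined &
                    .data$p_t >= high_conf)
}

#' Parent-of-origin weighted dosage encoding
#'
#' Applies the probability-weighted encoding to haploid parental dosages:
#' `DS_mat = AP_mat * p_t + AP_pat * (1 - p_t)` (and symmetrically for
#' `DS_pat`), `DS_dip = DS_mat + DS_pat`, genotype-probability triplets
#' `GP_mat = (1 - DS_mat, DS_mat, 0)` (likewise paternal), and the
#' differential triplet `GP_diff = (DS_mat/DS_dip, DS_pat/DS_dip, 0)`
#' defined at heterozygous entries only (homozygous entries are missing by
#' construction, as opposing parental contributions are indistinguishable
#' there). An uncertain assignment (`p_t = 0.5`) collapses the parental
#' dosages to equality.
#'
#' @param data Tibble with columns `ap_mat`, `ap_pat` in `[0, 1]` (any id
#'   columns are carried through). If a `p_t` column is present it is used.
#' @param p_t Parental assignment probability in `[0.5, 1]`, recycled
#'   (ignored when `data` has a `p_t` column).
#' @return `data` plus `ds_mat`, `ds_pat`, `ds_dip`, `het`, `gp_mat`,
#'   `gp_pat` (the heterozygote-probability component; the triplets follow
#'   as `(1 - x, x, 0)`), and `gp_diff_mat`, `gp_diff_pat` (`NA` off
#'   heterozygous entries or when `DS_dip = 0`).
#' @examples
#' encode_pofo(tibble::tibble(ap_mat = 1, ap_pat = 0), p_t = 0.9)
#' @export
encode_pofo <- function(data, p_t = 1) {
  stopifnot(all(c("ap_mat", "ap_pat") %in% names(data)))
  pt <- if ("p_t" %in% names(data)) data$p_t else rep_len(p_t, nrow(data))
  stopifnot(all(pt >= 0.5 & pt <= 1, na.rm = TRUE),
            all(data$ap_mat >= 0 & data$ap_mat <= 1),
            all(data$ap_pat >= 0 & data$ap_pat <= 1))
  out <- data
  out$ds_mat <- data$ap_mat * pt + data$ap_pat * (1 - pt)
  out$ds_pat <- data$ap_pat * pt + data$ap_mat * (1 - pt)
  out$ds_dip <- out$ds_mat + out$ds_pat
  out$het <- round(data$ap_mat) + round(data$ap_pat) == 1
  out$gp_mat <- out$ds_mat
  out$gp_pat <- out$ds_pat
  ok <- out$het & out$ds_dip > 0
  out$gp_diff_mat <- ifelse(ok, out$ds_mat / out$ds_dip, NA_real_)
  out$gp_diff_pat <- ifelse(ok, out$ds_pat / out$ds_dip, NA_real_)
  out
}

#' Matrix-backed parent-of-origin encoding
#'
#' Container for cohort-scale encodings: the same arithmetic as
#' [encode_pofo()], with individuals x variants matrices, per-variant
#' metadata and an individual-level probability vector. This is the input
#' of [assoc_scan()].
#'
#' @param ap_mat,ap_pat Numeric matrices (individuals x variants, dimnames
#'   required) of haploid maternal/paternal dosages.
#' @param p_t Named per-individual parental assignment probability (default
#'   1 for all).
#' @param variants Tibble with `variant_id` (matching columns), and
#'   optionally `chrom`, `pos`, `maf`, `info`.
#' @return An object of class `pofo_encoding`.
#' @export
pofo_encoding <- function(ap_mat, ap_pat, p_t = NULL, variants = NULL) {
  stopifnot(is.matrix(ap_mat), identical(dim(ap_mat), dim(ap_pat)),
            !is.null(rownames(ap_mat)), !is.null(colnames(ap_mat)))
  iid <- rownames(ap_mat)
  if (is.null(p_t)) p_t <- stats::setNames(rep(1, length(iid)), iid)
  pt <- p_t[iid]
  stopifnot(all(pt >= 0.5 & pt <= 1))
  ds_mat <- ap_mat * pt + ap_pat * (1 - pt)
  ds_pat <- ap_pat * pt + ap_mat * (1 - pt)
  het <- round(ap_mat) + round(ap_pat) == 1
  if (is.null(variants)) {
    variants <- tibble::tibble(variant_id = colnames(ap_mat))
  }
  structure(list(ds_mat = ds_mat, ds_pat = ds_pat,
                 ds_dip = ds_mat + ds_pat, het = het,
                 iid = iid, p_t = pt, variants = variants,
                 keep_variant = rep(TRUE, ncol(ap_mat)),
                 diff_ok = NULL),
            class = "pofo_encoding")
}

#' @export
print.pofo_encoding <- function(x, ...) {
  cat("<pofo_encoding> ", length(x$iid), " individuals x ",
      ncol(x$ds_mat), " variants (", sum(x$keep_variant),
      " pass variant filters)\n", sep = "")
  invisible(x)
}

#' @describeIn pofo_encoding Long-format view of an encoding.
#' @param x A `pofo_encoding`.
#' @param ... Unused.
#' @export
tidy.pofo_encoding <- function(x, ...) {
  tibble::tibble(
    iid = rep(x$iid, times = ncol(x$ds_mat)),
    variant_id = rep(colnames(x$ds_mat), each = length(x$iid)),
    ds_mat = as.vector(x$ds_mat), ds_pat = as.vector(x$ds_pat),
    ds_dip = as.vector(x$ds_dip), het = as.vector(x$het))
}

#' Variant and entry filters for association scans
#'
#' Marks variants passing the scan filters (imputation INFO above `info_min`
#' and minor allele frequency above `maf_min`), and, for the differential
#' scan, entries whose imputed parental dosage is confidently assigned
#' (`max(DS_mat, DS_pat)` above `dosage_certainty`), applied per individual
#' and variant.
#'
#' @param encoding A [pofo_encoding()] (the `variants` tibble must carry
#'   `info` and `maf`).
#' @param info_min INFO cutoff (default 0.8, exclusive).
#' @param maf_min MAF cutoff (default 0.01, exclusive).
#' @param dosage_certainty Parental-dosage certainty for differential
#'   entries (default 0.99, exclusive).
#' @return The encoding with `keep_variant` (logical per variant) and
#'   `diff_ok` (logical matrix) filled in.
#' @export
filter_variants <- function(encoding, info_min = 0.8, maf_min = 0.01,
                            dosage_certainty = 0.99) {
  stopifnot(inherits(encoding, "pofo_encoding"),
            all(c("info", "maf") %in% names(encoding$variants)))
  v <- encoding$variants
  maf <- pmin(v$maf, 1 - v$maf)
  encoding$keep_variant <- v$info > info_min & maf > maf_min
  encoding$diff_ok <- pmax(encoding$ds_mat, encoding$ds_pat) >
    dosage_certainty
  encoding
}
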