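#' Export a simulated cohort to VCF and TSV files
#'
#' Writes one phased VCF per autosome plus separate X and mtDNA VCFs
#' (`GT` with `|`-separated alleles; males carry a single X allele and
#' mtDNA is haploid), the sample metadata (`samples.tsv`: iid, sex coded
#' 1 = male / 2 = female, age), the genetic map (`map.tsv`: `pos chr
#' cM_female cM_male`), and the truth parent-of-origin of every haplotype
#' (`truth_pofo.tsv`: iid, chrom, hap_index, parent M/P).
#'
#' @param cohort A `pofo_cohort`.
#' @param dir Output directory (created if needed).
#' @param use Write `"observed"` or `"truth"` haplotypes.
#' @return Invisibly, the paths written.
#' @export
write_cohort_vcf <- function(cohort, dir, use = c("observed", "truth")) {
  use <- match.arg(use)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- cohort$samples$iid[cohort$samples$genotyped]
  src <- if (use == "observed") cohort$obs else cohort$haps
  paths <- character(0)
  vcf_header <- function(con, ids) {
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", ids),
                       collapse = "\t")), con)
  }
  write_chrom <- function(H, m, path, hap_cols = TRUE) {
    con <- file(path, "w")
    on.exit(close(con))
    vcf_header(con, ids)
    gt <- if (hap_cols) {
      a0 <- H[, paste0(ids, "|0"), drop = FALSE]
      a1 <- H[, paste0(ids, "|1"), drop = FALSE]
      g <- matrix(paste(a0, a1, sep = "|"), nrow = nrow(H))
      g[is.na(a0) & !is.na(a1)] <- paste0(a1[is.na(a0) & !is.na(a1)])
      g
    } else {
      matrix(as.character(H[, ids, drop = FALSE]), nrow = nrow(H))
    }
    body <- cbind(m$chrom, m$pos,
                  paste0(m$chrom, ":", m$pos), "A", "G", ".", "PASS",
                  ".", "GT", gt)
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
    path
  }
  for (ch in names(src)) {
    m <- cohort$map[cohort$map$chrom == ch, ]
    paths <- c(paths, write_chrom(src[[ch]], m,
                                  file.path(dir, paste0("chr", ch, ".vcf"))))
  }
  if (!is.null(cohort$x_haps)) {
    mx <- cohort$map[cohort$map$chrom == "X", ]
    paths <- c(paths, write_chrom(cohort$x_haps, mx,
                                  file.path(dir, "chrX.vcf")))
  }
  if (!is.null(cohort$mt)) {
    mt_m <- tibble::tibble(chrom = "MT", pos = seq_len(nrow(cohort$mt)))
    paths <- c(paths, write_chrom(cohort$mt, mt_m,
                                  file.path(dir, "mtdna.vcf"),
                                  hap_cols = FALSE))
  }
  readr::write_tsv(cohort$samples[cohort$samples$genotyped,
                                  c("iid", "sex", "age")],
                   file.path(dir, "samples.tsv"))
  readr::write_tsv(
    tibble::tibble(pos = cohort$map$pos, chr = cohort$map$chrom,
                   cM_female = cohort$map$cm_female,
                   cM_male = cohort$map$cm_male),
    file.path(dir, "map.tsv"))
  truth <- dplyr::bind_rows(lapply(names(cohort$haps), function(ch) {
    tibble::tibble(iid = rep(ids, each = 2), chrom = ch,
                   hap_index = rep(c(0L, 1L), length(ids)),
                   parent = rep(c("P", "M"), length(ids)))
  }))
  readr::write_tsv(truth, file.path(dir, "truth_pofo.tsv"))
  paths <- c(paths, file.path(dir, c("samples.tsv", "map.tsv",
                                     "truth_pofo.tsv")))
  invisible(paths)
}

#' Read phased haplotypes from a VCF
#'
#' Parses the `GT` field of a VCF (via `vcfR`) into the haplotype matrix
#' layout used throughout the package: columns `<iid>|0`, `<iid>|1`
#' (haploid samples get an all-`NA` first column, matching the X encoding
#' for males).
#'
#' @param path VCF file path.
#' @return List with `haps` (integer matrix, sites x 2N), `pos`, `chrom`,
#'   and `ids`.
#' @export
read_vcf_haplotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- colnames(gt)
  n <- nrow(gt)
  haps <- matrix(NA_integer_, n, 2L * length(ids))
  colnames(haps) <- paste0(rep(ids, each = 2L), "|", c(0L, 1L))
  for (j in seq_along(ids)) {
    parts <- strsplit(gt[, j], "|", fixed = TRUE)
    len <- lengths(parts)
    a0 <- ifelse(len == 2L, vapply(parts, `[`, "", 1L), NA)
    a1 <- ifelse(len == 2L, vapply(parts, `[`, "", 2L),
                 vapply(parts, `[`, "", 1L))
    haps[, 2L * j - 1L] <- suppressWarnings(as.integer(a0))
    haps[, 2L * j] <- suppressWarnings(as.integer(a1))
  }
  list(haps = haps,
       pos = as.numeric(vcfR::getPOS(v)),
       chrom = as.character(vcfR::getCHROM(v)),
       ids = ids)
}
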