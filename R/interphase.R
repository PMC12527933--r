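#' Parent-of-origin phasing from genotyped parents
#'
#' Resolves a child's alleles onto paternal/maternal haplotypes by
#' transmission logic. With one parent, the other side follows by exclusion
#' at sites where that parent is homozygous. Triple-heterozygous sites are
#' unresolvable by logic alone and returned unphased; Mendel-inconsistent
#' sites are masked.
#'
#' @param child Integer dosage vector 0/1/2.
#' @param father,mother Optional parental dosage vectors (at least one).
#' @return Tibble with `hap_pat`, `hap_mat` (0/1 alleles, `NA` when
#'   unresolved or masked), `resolved`, and `mendel_masked`.
#' @export
pedigree_phase <- function(child, father = NULL, mother = NULL) {
  if (is.null(father) && is.null(mother)) {
    stop("at least one parent is required", call. = FALSE)
  }
  n <- length(child)
  f <- father %||% rep(NA_integer_, n)
  m <- mother %||% rep(NA_integer_, n)
  hp <- hm <- rep(NA_integer_, n)
  masked <- rep(FALSE, n)
  bad_par <- function(p, c) !is.na(p) & ((p == 0L & c == 2L) | (p == 2L & c == 0L))
  masked <- bad_par(f, child) | bad_par(m, child) |
    (!is.na(f) & !is.na(m) &
       ((f == 0L & m == 0L & child != 0L) | (f == 2L & m == 2L & child != 2L) |
          (f + m == 2L & f != 1L & child != 1L)))
  hom <- !masked & child != 1L
  hp[hom] <- hm[hom] <- child[hom] %/% 2L
  het <- !masked & child == 1L
  # a homozygous parent pins its transmitted allele; the other follows
  f_hom <- het & !is.na(f) & f != 1L
  hp[f_hom] <- f[f_hom] %/% 2L
  hm[f_hom] <- 1L - hp[f_hom]
  m_hom <- het & is.na(hp) & !is.na(m) & m != 1L
  hm[m_hom] <- m[m_hom] %/% 2L
  hp[m_hom] <- 1L - hm[m_hom]
  tibble::tibble(hap_pat = hp, hap_mat = hm,
                 resolved = !is.na(hp), mendel_masked = masked)
}

#' Interchromosomal phasing from IBD anchors
#'
#' Re-orients an individual's observed haplotypes so that every IBD anchor
#' shared with surrogate-parent group G1 lies on haplotype index 0 and every
#' G2 anchor on index 1, across all chromosomes. Between consecutive anchors
#' demanding opposite orientations the flip point is placed at the physical
#' midpoint of the inter-anchor gap (the true switch position is
#' unidentifiable inside the gap). Intrachromosomal switch errors between
#' same-side anchors are corrected by the same mechanism. Chromosomes with no
#' anchors are left in their input orientation and flagged.
#'
#' @param haps Named list (chromosome -> `n_sites x 2` integer matrix) of one
#'   individual's observed haplotypes.
#' @param segments IBD segments for that individual as returned by
#'   [detect_ibd()] (needs `chrom`, `start_idx`, `end_idx`, `hap`, `group`,
#'   `n_sites`).
#' @param map Genetic map tibble.
#' @return List with `haps` (re-oriented), and `report`, a tibble per
#'   chromosome (`chrom`, `n_anchors`, `anchored`, `n_flips`).
#' @export
scaffold_phase <- function(haps, segments, map) {
  report <- list()
  out <- haps
  for (ch in names(haps)) {
    H <- haps[[ch]]
    m <- map[map$chrom == ch, ]
    a <- segments[segments$chrom == ch, , drop = FALSE]
    if (nrow(a) == 0) {
      report[[ch]] <- tibble::tibble(chrom = ch, n_anchors = 0L,
                                     anchored = FALSE, n_flips = 0L)
      next
    }
    a$req <- as.integer((a$hap == 0L & a$group == "G2") |
                          (a$hap == 1L & a$group == "G1"))
    a <- a[order(a$start_idx), , drop = FALSE]
    # overlapping anchors demanding opposite orientations: keep the larger
    keep <- rep(TRUE, nrow(a))
    if (nrow(a) > 1) {
      for (i in 2:nrow(a)) {
        prev <- max(which(keep[seq_len(i - 1)]))
        if (a$start_idx[i] <= a$end_idx[prev] && a$req[i] != a$req[prev]) {
          if (a$n_sites[i] > a$n_sites[prev]) keep[prev] <- FALSE
          else keep[i] <- FALSE
        }
      }
    }
    a <- a[keep, , drop = FALSE]
    o <- rep.int(a$req[1], nrow(H))
    n_flips <- 0L
    if (nrow(a) > 1) {
      for (i in 2:nrow(a)) {
        if (a$req[i] != a$req[i - 1]) {
          mid_bp <- (m$pos[a$end_idx[i - 1]] + m$pos[a$start_idx[i]]) / 2
          b <- findInterval(mid_bp, m$pos)
          o[seq_len(nrow(H)) > b] <- a$req[i]
          n_flips <- n_flips + 1L
        }
      }
    }
    swap <- o == 1L
    if (any(swap)) {
      tmp <- H[swap, 1L]
      H[swap, 1L] <- H[swap, 2L]
      H[swap, 2L] <- tmp
    }
    out[[ch]] <- H
    report[[ch]] <- tibble::tibble(chrom = ch, n_anchors = nrow(a),
                                   anchored = TRUE, n_flips = n_flips)
  }
  list(haps = out, report = dplyr::bind_rows(report))
}

#' Phasing accuracy metrics against truth
#'
#' Switch error rate: among consecutive pairs of truth-heterozygous sites
#' (within chromosomes), the fraction at which the inferred haplotype
#' orientation flips. Interchromosomal concordance: the fraction of
#' chromosomes whose majority-vote parental orientation agrees with the
#' genome-wide majority assignment.
#'
#' @param inferred,truth Named lists (chromosome -> `n_sites x 2` matrices)
#'   with haplotype index 0 carrying the same nominal parent in `truth`.
#' @return List with `switch_error_rate`, `interchromosomal_concordance`, and
#'   a per-chromosome tibble `per_chrom`.
#' @export
phasing_metrics <- function(inferred, truth) {
  per <- purrr::imap(truth, function(Tr, ch) {
    In <- inferred[[ch]]
    het <- Tr[, 1] != Tr[, 2]
    straight <- In[, 1] == Tr[, 1] & In[, 2] == Tr[, 2]
    crossed <- In[, 1] == Tr[, 2] & In[, 2] == Tr[, 1]
    o <- ifelse(straight, 0L, ifelse(crossed, 1L, NA_integer_))[het]
    o <- o[!is.na(o)]
    flips <- if (length(o) > 1) sum(diff(o) != 0) else 0L
    tibble::tibble(chrom = ch, n_het = length(o),
                   flips = flips, pairs = max(length(o) - 1L, 0L),
                   label = if (length(o)) as.integer(mean(o) > 0.5) else
                     NA_integer_)
  })
  per <- dplyr::bind_rows(per)
  genome <- as.integer(mean(per$label, na.rm = TRUE) > 0.5)
  list(
    switch_error_rate = sum(per$flips) / max(sum(per$pairs), 1L),
    interchromosomal_concordance =
      mean(per$label[!is.na(per$label)] == genome),
    per_chrom = per
  )
}
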