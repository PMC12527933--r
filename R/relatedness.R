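#' Pairwise kinship and IBS0
#'
#' Robust within-pair kinship estimator
#' `phi = (N_AaAa - 2 * N_IBS0) / (N_Aa(a) + N_Aa(b))`, where `N_AaAa` counts
#' sites at which both individuals are heterozygous, `N_IBS0` counts sites
#' sharing zero alleles identical by state, and `N_Aa(.)` are the per-sample
#' heterozygote counts. IBS0 is reported as a proportion of the overlapping
#' sites. Pairs with fewer than `min_sites` overlapping non-missing sites are
#' flagged (`ok = FALSE`) and their estimates set to `NA`.
#'
#' @param genotypes Integer matrix, sites x individuals, dosages 0/1/2
#'   (missing as `NA`), with column names.
#' @param pairs Tibble with columns `id_a`, `id_b`; default all pairs.
#' @param min_sites Minimum overlapping sites per pair.
#' @return Tibble `id_a`, `id_b`, `kinship`, `ibs0`, `n_sites`, `ok`.
#' @export
kinship_ibs <- function(genotypes, pairs = NULL, min_sites = 1000) {
  ids <- colnames(genotypes)
  stopifnot(!is.null(ids))
  if (is.null(pairs)) {
    cmb <- utils::combn(ids, 2)
    pairs <- tibble::tibble(id_a = cmb[1, ], id_b = cmb[2, ])
  }
  if (!anyNA(genotypes)) {
    # complete data: all pairwise counts via three cross-products
    H <- genotypes == 1L
    I0 <- genotypes == 0L
    I2 <- genotypes == 2L
    n_hh <- crossprod(H)
    n_ibs0 <- crossprod(I0, I2) + crossprod(I2, I0)
    het <- colSums(H)
    ia <- match(pairs$id_a, ids)
    ib <- match(pairs$id_b, ids)
    idx <- cbind(ia, ib)
    n <- nrow(genotypes)
    kin <- unname((n_hh[idx] - 2 * n_ibs0[idx]) / (het[ia] + het[ib]))
    out <- tibble::tibble(id_a = pairs$id_a, id_b = pairs$id_b,
                          kinship = kin, ibs0 = unname(n_ibs0[idx] / n),
                          n_sites = n, ok = n >= min_sites)
    out$kinship[!out$ok] <- NA_real_
    out$ibs0[!out$ok] <- NA_real_
    return(out)
  }
  est <- purrr::map2(pairs$id_a, pairs$id_b, function(a, b) {
    ga <- genotypes[, a]
    gb <- genotypes[, b]
    ok <- !is.na(ga) & !is.na(gb)
    n <- sum(ok)
    if (n < min_sites) {
      return(c(kinship = NA_real_, ibs0 = NA_real_, n = n, ok = 0))
    }
    ga <- ga[ok]; gb <- gb[ok]
    n_hh <- sum(ga == 1L & gb == 1L)
    n_ibs0 <- sum(abs(ga - gb) == 2L)
    het_a <- sum(ga == 1L)
    het_b <- sum(gb == 1L)
    c(kinship = (n_hh - 2 * n_ibs0) / (het_a + het_b),
      ibs0 = n_ibs0 / n, n = n, ok = 1)
  })
  est <- do.call(rbind, est)
  tibble::tibble(id_a = pairs$id_a, id_b = pairs$id_b,
                 kinship = est[, "kinship"], ibs0 = est[, "ibs0"],
                 n_sites = as.integer(est[, "n"]), ok = est[, "ok"] == 1)
}

#' Classify relative pairs
#'
#' Applies kinship/IBS0/age rules: parent-offspring for kinship in
#' `[0.1767, 0.3535]` with IBS0 below 0.0012 and an age gap above 15 years
#' (the older member is labelled the parent); sibling for the same kinship
#' range with IBS0 above 0.0012 and age gap below 15 years; 2nd/3rd/4th
#' degree by the half-interval kinship bins `[0.0884, 0.1767)`,
#' `[0.0442, 0.0884)`, `[0.0221, 0.0442)`; otherwise unrelated. Kinship above
#' 0.3535 is labelled `duplicate`. A first-degree pair with a missing age is
#' kept but labelled `first_degree` (parent-offspring/sibling suppressed).
#'
#' @param pair_table Output of [kinship_ibs()].
#' @param metadata Tibble with `iid`, `age` (and optionally `sex`).
#' @return `pair_table` with `age_difference`, `relationship`, and `parent`
#'   (the id of the inferred parent for parent-offspring pairs, else `NA`).
#' @export
classify_pairs <- function(pair_table, metadata) {
  age <- stats::setNames(metadata$age, metadata$iid)
  d <- pair_table |>
    dplyr::mutate(age_difference = age[.data$id_a] - age[.data$id_b])
  rel <- function(k, ibs0, dage) {
    if (is.na(k)) return(c("unknown", NA))
    if (k > 0.3535) return(c("duplicate", NA))
    if (k >= 0.1767) {
      if (is.na(dage)) return(c("first_degree", NA))
      if (ibs0 < 0.0012 && abs(dage) > 15) {
        return(c("parent_offspring", if (dage > 0) "a" else "b"))
      }
      if (ibs0 > 0.0012 && abs(dage) < 15) return(c("sibling", NA))
      return(c("first_degree", NA))
    }
    if (k >= 0.0884) return(c("second", NA))
    if (k >= 0.0442) return(c("third", NA))
    if (k >= 0.0221) return(c("fourth", NA))
    c("unrelated", NA)
  }
  lab <- purrr::pmap(list(d$kinship, d$ibs0, d$age_difference), rel)
  d$relationship <- vapply(lab, `[`, "", 1)
  who <- vapply(lab, `[`, "", 2)
  d$parent <- dplyr::case_when(who == "a" ~ d$id_a, who == "b" ~ d$id_b,
                               TRUE ~ NA_character_)
  d
}

#' Cluster a target's distant relatives into surrogate-parent sides
#'
#' Builds a graph over the target's 2nd-4th-degree relatives with edges where
#' two relatives are themselves related (kinship at least `min_kinship`);
#' connected components correspond to family sides. At most two sides are
#' retained (components beyond the two largest are dropped and flagged), and
#' the two groups are labelled `G1`/`G2` in decreasing size order - parental
#' labels are only assigned later by the X/mtDNA/sibling predictors.
#'
#' @param target Target individual id.
#' @param relatives Character vector of relative ids (degree 2-4).
#' @param pair_table Kinship table covering relative-relative pairs (either
#'   id order).
#' @param min_kinship Kinship edge threshold (default the 4th-degree lower
#'   bound, 0.0221).
#' @return Tibble `target`, `relative`, `group` (`"G1"`/`"G2"`); attribute
#'   `dropped` lists relatives from discarded extra components.
#' @export
cluster_surrogate_parents <- function(target, relatives, pair_table,
                                      min_kinship = 0.0221) {
  stopifnot(length(relatives) >= 1)
  relatives <- setdiff(unique(relatives), target)
  pt <- pair_table[pair_table$id_a %in% relatives &
                     pair_table$id_b %in% relatives, ]
  pt <- pt[!is.na(pt$kinship) & pt$kinship >= min_kinship, ]
  g <- igraph::graph_from_data_frame(
    pt[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = relatives))
  comp <- igraph::components(g)
  sizes <- sort(table(comp$membership), decreasing = TRUE)
  keep <- as.integer(names(sizes)[seq_len(min(2L, length(sizes)))])
  grp <- stats::setNames(rep(NA_character_, length(relatives)), relatives)
  grp[names(comp$membership)[comp$membership == keep[1]]] <- "G1"
  if (length(keep) > 1) {
    grp[names(comp$membership)[comp$membership == keep[2]]] <- "G2"
  }
  out <- tibble::tibble(target = target, relative = names(grp),
                        group = unname(grp)) |>
    dplyr::filter(!is.na(.data$group))
  attr(out, "dropped") <- names(grp)[is.na(grp)]
  out
}

#' Mendel error rate of a trio
#'
#' Fraction of sites at which the child's genotype is impossible given both
#' parents under Mendelian transmission.
#'
#' @param child,father,mother Integer dosage vectors 0/1/2 over the same
#'   sites (`NA` sites are skipped).
#' @return A single rate in `[0, 1]`.
#' @export
mendel_error_rate <- function(child, father, mother) {
  ok <- !is.na(child) & !is.na(father) & !is.na(mother)
  c <- child[ok]; f <- father[ok]; m <- mother[ok]
  err <- (f == 0L & c == 2L) | (f == 2L & c == 0L) |
    (m == 0L & c == 2L) | (m == 2L & c == 0L) |
    (f == 0L & m == 0L & c != 0L) | (f == 2L & m == 2L & c != 2L) |
    (f == 0L & m == 2L & c != 1L) | (f == 2L & m == 0L & c != 1L)
  mean(err)
}
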