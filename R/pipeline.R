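#' End-to-end parent-of-origin inference over a cohort
#'
#' Runs the full inference chain on a simulated (or compatibly structured)
#' cohort: pairwise kinship and relationship classification; surrogate-parent
#' clustering of 2nd-4th-degree relatives; IBD scanning and interchromosomal
#' scaffold phasing (haplotype 0 carries group G1 genome-wide);
#' parental-side prediction of G1 from X-chromosome sharing (male targets)
#' and mtDNA minor-variant sharing; genome-wide sibling crossover scores for
#' scaffolded targets with a sibling; pedigree phasing where a genotyped
#' parent exists; and predictor combination into one call per target.
#' Sibling-pair targets without any surrogate-parent scaffold receive
#' single-chromosome threshold calls instead of a genome-wide call.
#'
#' @param cohort A `pofo_cohort`.
#' @param pair_table Optional precomputed [kinship_ibs()] table (computed
#'   from observed genotypes when `NULL`).
#' @param x_calibration,mvs_calibration [side_calibration()] tables for the
#'   X and MVS predictors (predictor skipped when `NULL`).
#' @param sib_validation Validation tibble for [prob_pofo_sib()] (`s`, `l`,
#'   `parent_h0`); sibling genome scores are skipped when `NULL`.
#' @param min_sites_kinship Minimum overlapping sites for kinship.
#' @param min_cm,min_sites IBD detection floors (see [detect_ibd()]).
#' @param high_conf High-confidence probability flag cutoff.
#' @param targets Targets to infer (default: all genotyped individuals with
#'   role `"target"`); restrict e.g. to a held-out evaluation set when the
#'   calibration tables were built from other families of the same cohort.
#' @return A list with `calls` (one row per genome-wide-called target),
#'   `chrom_calls` (per-chromosome sibling threshold calls), `predictions`
#'   (all raw predictor rows), `phased` (named list of re-oriented haplotype
#'   lists per scaffolded target), `relative_sets`, and `pair_table`.
#' @export
infer_cohort_pofo <- function(cohort, pair_table = NULL,
                              x_calibration = NULL, mvs_calibration = NULL,
                              sib_validation = NULL,
                              min_sites_kinship = 500,
                              min_cm = 3, min_sites = 20, high_conf = 0.99,
                              targets = NULL) {
  stopifnot(inherits(cohort, "pofo_cohort"))
  smp <- cohort$samples
  gids <- smp$iid[smp$genotyped]
  G <- cohort_genotypes(cohort, use = "observed")
  if (is.null(pair_table)) {
    pair_table <- kinship_ibs(G, min_sites = min_sites_kinship)
  }
  pt <- classify_pairs(pair_table, smp)
  partners <- function(iid, rel) {
    sel <- pt$relationship == rel & (pt$id_a == iid | pt$id_b == iid)
    setdiff(c(pt$id_a[sel], pt$id_b[sel]), iid)
  }
  targets <- targets %||% smp$iid[smp$genotyped & smp$role == "target"]
  chroms <- names(cohort$obs)
  lens <- map_lengths(cohort$map)

  preds <- list()
  chrom_calls <- list()
  phased <- list()
  rel_sets <- list()
  reports <- list()

  for (tg in targets) {
    my_parents <- pt$parent[!is.na(pt$parent) &
                              (pt$id_a == tg | pt$id_b == tg) &
                              pt$parent != tg]
    rels <- unlist(lapply(c("second", "third", "fourth"), partners, iid = tg))
    sibs <- partners(tg, "sibling")
    t_obs <- purrr::map(chroms, ~cohort_haps(cohort, tg, .x, "observed"))
    names(t_obs) <- chroms
    scaffolded <- FALSE

    if (length(my_parents) > 0) {
      # genotyped parent(s): pedigree PofO phasing, paternal on haplotype 0
      fa <- intersect(my_parents, smp$iid[smp$sex == 1L])
      mo <- intersect(my_parents, smp$iid[smp$sex == 2L])
      ph <- purrr::map(chroms, function(ch) {
        gt <- function(id) {
          h <- cohort_haps(cohort, id, ch, "observed"); h[, 1] + h[, 2]
        }
        r <- pedigree_phase(gt(tg),
                            father = if (length(fa)) gt(fa[1]) else NULL,
                            mother = if (length(mo)) gt(mo[1]) else NULL)
        cbind(`0` = r$hap_pat, `1` = r$hap_mat)
      })
      names(ph) <- chroms
      phased[[tg]] <- ph
      preds[[length(preds) + 1L]] <- tibble::tibble(
        target = tg, predictor = "PED", parent_h0 = "pat", prob = 1,
        degree = 1L)
      next
    }

    if (length(rels) > 0) {
      rs <- cluster_surrogate_parents(tg, rels, pair_table)
      rel_sets[[tg]] <- rs
      segs <- purrr::map(chroms, function(ch) {
        dplyr::bind_rows(purrr::map(c("G1", "G2"), function(g) {
          mem <- rs$relative[rs$group == g]
          if (!length(mem)) return(NULL)
          gh <- purrr::map(mem, ~cohort_haps(cohort, .x, ch, "observed"))
          names(gh) <- mem
          detect_ibd(t_obs[[ch]], gh, cohort$map, ch, group = g,
                     min_cm = min_cm, min_sites = min_sites)
        }))
      }) |> dplyr::bind_rows()
      sp <- scaffold_phase(t_obs, segs, cohort$map)
      phased[[tg]] <- sp$haps
      reports[[tg]] <- dplyr::mutate(sp$report, target = tg, .before = 1)
      scaffolded <- any(sp$report$anchored)

      # parental side of G1 from X sharing (male targets: surrogate fathers
      # share no X) and from mtDNA MVS per relative; G2 evidence converts to
      # G1 by the two-sides assumption.
      x_cols <- paste0(tg, "|", 0:1)
      if (!is.null(x_calibration) && !is.null(cohort$x_haps) &&
          smp$sex[smp$iid == tg] == 1L) {
        tx <- cohort$x_haps[, x_cols, drop = FALSE]
        for (g in unique(rs$group)) {
          mem <- rs$relative[rs$group == g]
          gx <- purrr::map(mem, function(id) {
            cohort$x_haps[, paste0(id, "|", 0:1), drop = FALSE]
          })
          names(gx) <- mem
          l <- longest_x_share(tx, gx, cohort$map,
                               min_cm = min_cm, min_sites = min_sites)
          p <- prob_side_x(l, x_calibration)
          pr_pat_g1 <- if (g == "G1") p$pr_pat else p$pr_mat
          preds[[length(preds) + 1L]] <- tibble::tibble(
            target = tg, predictor = "X",
            parent_h0 = ifelse(pr_pat_g1 >= 0.5, "pat", "mat"),
            prob = pmax(pr_pat_g1, 1 - pr_pat_g1),
            degree = min(pt_degree(pt, tg, mem)))
        }
      }
      if (!is.null(mvs_calibration) && !is.null(cohort$mt)) {
        for (i in seq_len(nrow(rs))) {
          rel <- rs$relative[i]
          deg <- pt_degree(pt, tg, rel)
          v <- mvs(cohort$mt[, tg], cohort$mt[, rel])
          p <- prob_side_mvs(v, deg, mvs_calibration)
          if (is.na(p$prob)) next
          pr_pat_g1 <- if (rs$group[i] == "G1") p$pr_pat else p$pr_mat
          preds[[length(preds) + 1L]] <- tibble::tibble(
            target = tg, predictor = "MT",
            parent_h0 = ifelse(pr_pat_g1 >= 0.5, "pat", "mat"),
            prob = pmax(pr_pat_g1, 1 - pr_pat_g1), degree = deg)
        }
      }
    }

    if (length(sibs) > 0) {
      sib_obs <- purrr::map(chroms,
                            ~cohort_haps(cohort, sibs[1], .x, "observed"))
      names(sib_obs) <- chroms
      if (scaffolded && !is.null(sib_validation)) {
        sc <- sib_pair_score(phased[[tg]], sib_obs, cohort$map,
                             min_cm = min_cm, min_sites = min_sites)
        pr <- prob_pofo_sib(sc$s, sc$l, sib_validation)
        preds[[length(preds) + 1L]] <- tibble::tibble(
          target = tg, predictor = "SIB", parent_h0 = pr$side,
          prob = pr$prob, degree = 1L)
      } else if (!scaffolded) {
        sc <- sib_pair_score(t_obs, sib_obs, cohort$map,
                             min_cm = min_cm, min_sites = min_sites)
        cc <- sc$chrom_scores
        if (nrow(cc)) {
          cc$parent_h0 <- single_chrom_assign(cc$s_c)
          chrom_calls[[length(chrom_calls) + 1L]] <-
            dplyr::mutate(cc[!is.na(cc$parent_h0),
                             c("chrom", "s_c", "parent_h0")],
                          target = tg, .before = 1)
        }
      }
    }
  }

  predictions <- if (length(preds)) dplyr::bind_rows(preds) else
    tibble::tibble(target = character(), predictor = character(),
                   parent_h0 = character(), prob = numeric(),
                   degree = integer())
  calls <- if (nrow(predictions)) {
    combine_predictors(predictions, high_conf = high_conf)
  } else {
    tibble::tibble(target = character(), parent_h0 = character(),
                   p_t = numeric(), predictor = character(),
                   determined = logical(), high_confidence = logical())
  }
  list(calls = calls,
       chrom_calls = if (length(chrom_calls)) dplyr::bind_rows(chrom_calls)
       else tibble::tibble(target = character(), chrom = character(),
                           s_c = numeric(), parent_h0 = character()),
       predictions = predictions, phased = phased,
       reports = if (length(reports)) dplyr::bind_rows(reports) else
         tibble::tibble(target = character(), chrom = character(),
                        n_anchors = integer(), anchored = logical(),
                        n_flips = integer()),
       relative_sets = rel_sets, pair_table = pair_table)
}

# degree of the closest classified relationship between a target and any of
# the given relatives (2/3/4; NA when unclassified)
pt_degree <- function(pt, tg, rels) {
  deg <- c(second = 2L, third = 3L, fourth = 4L)
  sel <- (pt$id_a == tg & pt$id_b %in% rels) |
    (pt$id_b == tg & pt$id_a %in% rels)
  d <- deg[pt$relationship[sel]]
  if (all(is.na(d))) NA_integer_ else min(d, na.rm = TRUE)
}

#' Truth parent of haplotype 0
#'
#' Majority-vote comparison of an inferred haplotype set against the
#' cohort's truth haplotypes (haplotype 0 paternal), per chromosome and
#' genome-wide - the evaluation used to score inferred PofO calls.
#'
#' @param cohort A `pofo_cohort`.
#' @param iid Individual id.
#' @param haps Named list (chromosome -> `n_sites x 2`) of inferred
#'   haplotypes; defaults to the observed haplotypes.
#' @param chroms Chromosomes to evaluate (default all autosomes); restrict
#'   to scaffold-anchored chromosomes when judging a PofO call, since
#'   unanchored chromosomes keep their arbitrary input orientation.
#' @return List with `genome` (`"pat"`/`"mat"`: the truth parent of inferred
#'   haplotype 0) and `per_chrom` tibble.
#' @export
hap0_truth_parent <- function(cohort, iid, haps = NULL, chroms = NULL) {
  chroms <- chroms %||% names(cohort$haps)
  haps <- haps %||% {
    h <- purrr::map(chroms, ~cohort_haps(cohort, iid, .x, "observed"))
    names(h) <- chroms
    h
  }
  haps <- haps[chroms]
  truth <- purrr::map(chroms, ~cohort_haps(cohort, iid, .x, "truth"))
  names(truth) <- chroms
  if (length(chroms) == 0) {
    return(list(genome = NA_character_,
                per_chrom = tibble::tibble(chrom = character(),
                                           label = integer(),
                                           parent_h0 = character())))
  }
  m <- phasing_metrics(haps, truth)
  per <- dplyr::mutate(
    m$per_chrom,
    parent_h0 = dplyr::case_when(.data$label == 0L ~ "pat",
                                 .data$label == 1L ~ "mat"))
  votes <- stats::na.omit(per$label)
  list(genome = if (length(votes)) c("pat", "mat")[1 + (mean(votes) > 0.5)]
       else NA_character_,
       per_chrom = per)
}
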