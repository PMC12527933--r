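# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

# moderate mixed-family cohort reused across test files
fix_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    cfg <- sim_config(
      n_families = 40, seed = 101,
      family_mix = c(trio = 0.2, duo = 0.1, sibling = 0.2,
                     second = 0.3, third = 0.1, fourth = 0.1),
      map_args = list(n_chrom = 6, n_sites = 3000, include_x = TRUE,
                      x_sites = 800))
    .fixtures$cohort <- simulate_cohort(cfg)
  }
  .fixtures$cohort
}

fix_map <- function() fix_cohort()$map

# brute-force piecewise-linear interpolation oracle
bf_interp <- function(m, bp, col) {
  vapply(bp, function(x) {
    if (x <= m$pos[1]) return(m[[col]][1])
    n <- nrow(m)
    if (x >= m$pos[n]) return(m[[col]][n])
    i <- max(which(m$pos <= x))
    if (m$pos[i] == x) return(m[[col]][i])
    w <- (x - m$pos[i]) / (m$pos[i + 1] - m$pos[i])
    m[[col]][i] * (1 - w) + m[[col]][i + 1] * w
  }, 0)
}

# brute-force exact-run IBD oracle: maximal equal runs between two
# haplotypes, filtered by marker count and sex-averaged cM length
bf_exact_segments <- function(a, b, m, min_cm = 3, min_sites = 20) {
  cm <- (m$cm_female + m$cm_male) / 2
  eq <- !is.na(a) & !is.na(b) & a == b
  out <- NULL
  i <- 1
  n <- length(eq)
  while (i <= n) {
    if (eq[i]) {
      j <- i
      while (j < n && eq[j + 1]) j <- j + 1
      if (j - i + 1 >= min_sites && cm[j] - cm[i] >= min_cm) {
        out <- rbind(out, c(start_idx = i, end_idx = j))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# X sharing length between a target and a single relative
x_share_len <- function(cohort, target, relative, ...) {
  tx <- cohort$x_haps[, paste0(target, "|", 0:1), drop = FALSE]
  gx <- list(cohort$x_haps[, paste0(relative, "|", 0:1), drop = FALSE])
  names(gx) <- relative
  longest_x_share(tx, gx, cohort$map, ...)
}

# calibration tables from a set of families of a cohort, using truth sides
# but kinship-classified relative degrees (matching what prediction sees)
build_side_calibrations <- function(cohort, classified, families) {
  smp <- cohort$samples
  deg_map <- c(second = 2L, third = 3L, fourth = 4L)
  rows <- cohort$sides[cohort$sides$degree >= 2 &
                         smp$family[match(cohort$sides$target, smp$iid)] %in%
                           families, ]
  cdeg <- l <- v <- rep(NA_real_, nrow(rows))
  male <- logical(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    tg <- rows$target[i]; rel <- rows$relative[i]
    sel <- (classified$id_a == tg & classified$id_b == rel) |
      (classified$id_b == tg & classified$id_a == rel)
    r <- classified$relationship[sel][1]
    if (!r %in% names(deg_map)) next
    cdeg[i] <- deg_map[[r]]
    male[i] <- smp$sex[smp$iid == tg] == 1L
    l[i] <- x_share_len(cohort, tg, rel)
    v[i] <- mvs(cohort$mt[, tg], cohort$mt[, rel])
  }
  keep <- !is.na(cdeg)
  list(
    x = side_calibration(l[keep & male], rows$side[keep & male]),
    mvs = side_calibration(v[keep], rows$side[keep], stratum = cdeg[keep]))
}

# high-confidence genome-wide call accuracy against simulator truth,
# judged over scaffold-anchored chromosomes
highconf_accuracy <- function(cohort, res) {
  calls <- res$calls[res$calls$determined, ]
  truth <- vapply(seq_len(nrow(calls)), function(i) {
    tg <- calls$target[i]
    anc <- if (calls$predictor[i] == "PED") names(cohort$haps) else
      res$reports$chrom[res$reports$target == tg & res$reports$anchored]
    hap0_truth_parent(cohort, tg, res$phased[[tg]], chroms = anc)$genome
  }, "")
  ok <- !is.na(truth)
  hc <- ok & calls$high_confidence
  list(accuracy = mean(calls$parent_h0[hc] == truth[hc]),
       n = sum(hc),
       all_accuracy = mean(calls$parent_h0[ok] == truth[ok]))
}
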