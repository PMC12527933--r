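# Identity-run scanner: maximal match runs between two haplotypes, bridging
# isolated single-site mismatches while the block's mismatch rate stays at or
# below `tol`; two or more consecutive mismatches always split. Missing
# alleles count as mismatches. Returns a matrix (start_idx, end_idx, n_mm).
match_runs <- function(a, b, tol = 0.01) {
  match <- !is.na(a) & !is.na(b) & a == b
  r <- rle(match)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  blocks <- vector("list", length(r$lengths))
  nb <- 0L
  cur <- NULL # c(start, end, n_mm)
  i <- 1L
  n_runs <- length(r$lengths)
  while (i <= n_runs) {
    if (r$values[i]) {
      if (is.null(cur)) {
        cur <- c(starts[i], ends[i], 0L)
      } else {
        cur[2] <- ends[i]
      }
      i <- i + 1L
    } else {
      bridge <- !is.null(cur) && r$lengths[i] == 1L && i < n_runs &&
        r$values[i + 1L] &&
        (cur[3] + 1L) / (ends[i + 1L] - cur[1] + 1L) <= tol
      if (bridge) {
        cur[3] <- cur[3] + 1L
        cur[2] <- ends[i + 1L]
        i <- i + 2L
      } else {
        if (!is.null(cur)) {
          nb <- nb + 1L
          blocks[[nb]] <- cur
          cur <- NULL
        }
        i <- i + 1L
      }
    }
  }
  if (!is.null(cur)) {
    nb <- nb + 1L
    blocks[[nb]] <- cur
  }
  out <- if (nb) matrix(unlist(blocks[seq_len(nb)]), ncol = 3,
                        byrow = TRUE) else matrix(integer(0), ncol = 3)
  colnames(out) <- c("start", "end", "n_mm")
  out
}

# Interval union over site indices; input tibble-like with start_idx/end_idx.
merge_index_intervals <- function(s, e) {
  o <- order(s)
  s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]
  out_s <- integer(0); out_e <- integer(0)
  if (length(s) > 1) {
    for (i in 2:length(s)) {
      if (s[i] <= me + 1L) {
        me <- max(me, e[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- s[i]; me <- e[i]
      }
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Detect IBD segments between a target and a surrogate-parent group
#'
#' Scans each target haplotype against every haplotype of every group member
#' for maximal identity runs (allowing a bounded mismatch rate, see
#' `max_mismatch_rate`; runs split at two or more consecutive mismatches).
#' Segments shorter than `min_cm` (sex-averaged) or covering fewer than
#' `min_sites` markers are discarded; the marker-count guard suppresses
#' chance identity-by-state runs across recombination hotspots where few
#' markers span many centimorgans. Overlapping segments from members of the
#' same group are merged.
#'
#' @param target_haps Integer matrix `n_sites x k` (k = 1 or 2), the target's
#'   haplotypes on one chromosome.
#' @param group_haps Named list (member id -> `n_sites x k` matrix) of the
#'   group members' haplotypes on the same marker grid.
#' @param map Genetic map tibble.
#' @param chrom Chromosome of the marker grid.
#' @param group Group label stored on the segments (e.g. `"G1"`).
#' @param min_cm Minimum segment length in sex-averaged cM (default 3).
#' @param min_sites Minimum markers per segment (default 20).
#' @param max_mismatch_rate Mismatch tolerance inside a segment (default
#'   0.01); set to 0 for exact runs.
#' @return Tibble with columns `chrom`, `start`, `end` (bp, 0-based
#'   half-open), `cm`, `hap` (target haplotype index 0/1), `group`, `member`,
#'   `n_sites`, `start_idx`, `end_idx` (1-based marker indices).
#' @export
detect_ibd <- function(target_haps, group_haps, map, chrom, group = "G1",
                       min_cm = 3, min_sites = 20, max_mismatch_rate = 0.01) {
  m <- map[map$chrom == chrom, ]
  stopifnot(nrow(m) == nrow(target_haps))
  cm_avg <- (m$cm_female + m$cm_male) / 2
  p_hap <- integer(0)
  p_mem <- character(0)
  p_s <- integer(0)
  p_e <- integer(0)
  for (h in seq_len(ncol(target_haps))) {
    for (mem in names(group_haps)) {
      gh <- group_haps[[mem]]
      for (k in seq_len(ncol(gh))) {
        if (all(is.na(gh[, k]))) next
        runs <- match_runs(target_haps[, h], gh[, k], tol = max_mismatch_rate)
        if (nrow(runs) == 0) next
        keep <- (runs[, "end"] - runs[, "start"] + 1L) >= min_sites &
          (cm_avg[runs[, "end"]] - cm_avg[runs[, "start"]]) >= min_cm
        runs <- runs[keep, , drop = FALSE]
        if (nrow(runs) == 0) next
        p_hap <- c(p_hap, rep.int(h - 1L, nrow(runs)))
        p_mem <- c(p_mem, rep.int(mem, nrow(runs)))
        p_s <- c(p_s, runs[, "start"])
        p_e <- c(p_e, runs[, "end"])
      }
    }
  }
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), cm = numeric(), hap = integer(),
                          group = character(), member = character(),
                          n_sites = integer(), start_idx = integer(),
                          end_idx = integer())
  if (!length(p_s)) return(empty)
  # merge overlapping segments from members of the same group, per haplotype
  o_hap <- integer(0)
  o_mem <- character(0)
  o_s <- integer(0)
  o_e <- integer(0)
  for (h in unique(p_hap)) {
    sel <- p_hap == h
    iv <- merge_index_intervals(p_s[sel], p_e[sel])
    mem <- vapply(seq_len(nrow(iv)), function(i) {
      inside <- sel & p_s >= iv[i, "start"] & p_e <= iv[i, "end"]
      p_mem[inside][which.max(p_e[inside] - p_s[inside])]
    }, "")
    o_hap <- c(o_hap, rep.int(h, nrow(iv)))
    o_mem <- c(o_mem, mem)
    o_s <- c(o_s, iv[, "start"])
    o_e <- c(o_e, iv[, "end"])
  }
  ord <- order(o_hap, o_s)
  n_out <- length(ord)
  tibble::new_tibble(list(
    chrom = rep.int(chrom, n_out),
    start = as.numeric(m$pos[o_s[ord]]),
    end = as.numeric(m$pos[o_e[ord]] + 1),
    cm = cm_avg[o_e[ord]] - cm_avg[o_s[ord]],
    hap = o_hap[ord],
    group = rep.int(group, n_out),
    member = o_mem[ord],
    n_sites = o_e[ord] - o_s[ord] + 1L,
    start_idx = o_s[ord],
    end_idx = o_e[ord]), nrow = n_out)
}

#' Longest X-chromosome sharing with a surrogate-parent group
#'
#' Largest IBD segment length (cM) between any of the target's X haplotypes
#' (one for males, both for females) and any group member's X. Surrogate
#' fathers of a male target share no X transmission path, so their lengths
#' concentrate near zero; surrogate mothers share long segments.
#'
#' @param target_x Matrix `n_sites x 1` (male) or `n_sites x 2` (female); an
#'   all-`NA` column is ignored.
#' @param group_x Named list of group members' X haplotype matrices.
#' @param map Genetic map including chromosome `"X"`.
#' @param ... Passed to [detect_ibd()] (detection floor etc.).
#' @return Largest shared length in cM (0 when no segment clears the floor).
#' @export
longest_x_share <- function(target_x, group_x, map, ...) {
  if (is.null(target_x) || all(is.na(target_x))) {
    stop("no X data for target", call. = FALSE)
  }
  target_x <- target_x[, colSums(!is.na(target_x)) > 0, drop = FALSE]
  seg <- detect_ibd(target_x, group_x, map, chrom = "X", ...)
  if (nrow(seg) == 0) 0 else max(seg$cm)
}
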