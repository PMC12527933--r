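#' Infer crossovers from sibling IBD segments
#'
#' IBD segment breakends between a sibling pair are crossover positions: a
#' boundary where the sharing state of a target haplotype changes reflects a
#' crossover in one of the two meioses of the parent who transmitted that
#' haplotype (both siblings' haplotypes contribute, so four meioses feed the
#' genome-wide expectation lambda = 4 l_c). Chromosome ends are not
#' breakends. Each breakend is placed at the physical midpoint between the
#' last shared and the first non-shared marker, i.e. inside the marker
#' interval that contains the crossover.
#'
#' @param segments IBD segments of one target against one sibling
#'   ([detect_ibd()] output; `hap` is the target haplotype index, and
#'   `start_idx`/`end_idx` are marker indices on the map grid).
#' @param map Genetic map tibble (defines the chromosome marker spans).
#' @return Tibble `chrom`, `pos` (bp), `hap` - one row per crossover call.
#' @export
infer_crossovers <- function(segments, map) {
  empty <- tibble::tibble(chrom = character(), pos = numeric(),
                          hap = integer())
  if (nrow(segments) == 0) return(empty)
  o_ch <- character(0)
  o_pos <- numeric(0)
  o_hap <- integer(0)
  for (ch in unique(segments$chrom)) {
    d <- segments[segments$chrom == ch, ]
    p <- map$pos[map$chrom == ch]
    n <- length(p)
    s_in <- d$start_idx > 1L
    e_in <- d$end_idx < n
    pos <- c((p[d$start_idx[s_in] - 1L] + p[d$start_idx[s_in]]) / 2,
             (p[d$end_idx[e_in]] + p[d$end_idx[e_in] + 1L]) / 2)
    o_ch <- c(o_ch, rep.int(ch, length(pos)))
    o_pos <- c(o_pos, pos)
    o_hap <- c(o_hap, c(d$hap[s_in], d$hap[e_in]))
  }
  if (!length(o_pos)) return(empty)
  ord <- order(o_ch, o_hap, o_pos)
  tibble::new_tibble(list(chrom = o_ch[ord], pos = o_pos[ord],
                          hap = o_hap[ord]), nrow = length(ord))
}

#' Sex-map contrast of a crossover window
#'
#' For each crossover a 1,000-bp window (`pos` +/- 500, clamped to the map)
#' is converted to genetic lengths `D_f`, `D_m` (Morgans) on the female and
#' male maps; the contrast is `delta = log10(D_f) - log10(D_m)`. Lengths are
#' floored at 1e-8 Morgan so map plateaus cannot produce infinities. A
#' negative delta marks a window where male recombination dominates, i.e. a
#' crossover more likely of paternal origin.
#'
#' @param calls Crossover tibble (`chrom`, `pos`, `hap`).
#' @param map Genetic map tibble.
#' @param window_bp Window width in bp (default 1000).
#' @param floor_morgan Lower floor on window lengths (default 1e-8).
#' @return `calls` with columns `d_f`, `d_m` (Morgans) and `delta`.
#' @export
crossover_delta <- function(calls, map, window_bp = 1000, floor_morgan = 1e-8) {
  if (nrow(calls) == 0) {
    return(dplyr::mutate(calls, d_f = numeric(0), d_m = numeric(0),
                         delta = numeric(0)))
  }
  d_f <- d_m <- rep(NA_real_, nrow(calls))
  for (ch in unique(calls$chrom)) {
    sel <- which(calls$chrom == ch)
    lo <- interpolate_cm(map, ch, calls$pos[sel] - window_bp / 2)
    hi <- interpolate_cm(map, ch, calls$pos[sel] + window_bp / 2)
    d_f[sel] <- pmax((hi$cm_female - lo$cm_female) / 100, floor_morgan)
    d_m[sel] <- pmax((hi$cm_male - lo$cm_male) / 100, floor_morgan)
  }
  out <- calls
  out$d_f <- d_f
  out$d_m <- d_m
  out$delta <- log10(d_f) - log10(d_m)
  out
}

#' Per-chromosome crossover scores
#'
#' `S_c = sum(delta over haplotype-0 calls) - sum(delta over haplotype-1
#' calls)`. A negative score favours haplotype 0 being paternally inherited.
#'
#' @param calls Crossover calls with `delta` (see [crossover_delta()]).
#' @return Tibble `chrom`, `s_c`, `n0`, `n1`, `n_obs`.
#' @export
chrom_scores <- function(calls) {
  calls |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::summarise(
      s_c = sum(.data$delta[.data$hap == 0L]) -
        sum(.data$delta[.data$hap == 1L]),
      n0 = sum(.data$hap == 0L), n1 = sum(.data$hap == 1L),
      n_obs = dplyr::n(), .groups = "drop")
}

#' Genome-wide crossover score
#'
#' Sum of per-chromosome scores over interchromosomally phased chromosomes.
#'
#' @param scores Output of [chrom_scores()].
#' @return A single number `S`.
#' @export
genome_score <- function(scores) sum(scores$s_c)

#' Crossover-count quality control
#'
#' Flags, per chromosome, individuals whose observed crossover count deviates
#' from the cohort distribution by more than `k` times the interquartile
#' range (expected counts follow Poisson with mean `4 l_c`, but IBD-mapper
#' artefacts inflate counts for some individuals). When the cohort IQR is
#' degenerate (0), a Poisson tail test at `p_fallback` against `4 l_c` is
#' used instead.
#'
#' @param counts Tibble `iid`, `chrom`, `n_obs` across the cohort.
#' @param lengths Map lengths ([map_lengths()] output; needs `chrom`, `l_c`).
#' @param k IQR multiplier (default 10).
#' @param p_fallback Poisson tail probability for the degenerate-IQR
#'   fallback (default 1e-6).
#' @return `counts` with logical `keep`.
#' @export
qc_crossovers <- function(counts, lengths, k = 10, p_fallback = 1e-6) {
  counts |>
    dplyr::left_join(lengths[, c("chrom", "l_c")], by = "chrom") |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      keep = {
        q <- stats::quantile(.data$n_obs, c(0.25, 0.75), names = FALSE)
        iqr <- q[2] - q[1]
        if (iqr > 0) {
          .data$n_obs >= q[1] - k * iqr & .data$n_obs <= q[2] + k * iqr
        } else {
          lam <- 4 * .data$l_c
          stats::ppois(.data$n_obs - 1, lam, lower.tail = FALSE) > p_fallback
        }
      }) |>
    dplyr::ungroup() |>
    dplyr::select(-"l_c")
}

#' Parent-of-origin probability from the genome-wide sibling score
#'
#' Compares a target's score `S_t` to validation-cohort scores of
#' individuals with known haplotype-0 parent and similar analysed genomic
#' length (within `(l_t - 3, l_t + 3)` Morgans), through the empirical-ratio
#' estimator: for scores below the class-separating cut the paternal form
#' `Pr_pat = [N_pat^-1 sum I(S_i < S_t)] /
#'   [N_pat^-1 sum I(S_i < S_t) + N_mat^-1 sum I(S_i < S_t)]`,
#' above it the symmetric "greater than" maternal form, with
#' `Pr_mat = 1 - Pr_pat` (negative scores are compatible with paternal
#' inheritance of haplotype 0). An empty length window is widened stepwise
#' (with a warning) until both truth classes are represented.
#'
#' @param s_t Target score.
#' @param l_t Genomic length analysed for the target, in Morgans.
#' @param validation Tibble `s` (score), `l` (Morgans), `parent_h0`
#'   (`"pat"`/`"mat"`) for the validation cohort.
#' @param window Half-width of the length window in Morgans (default 3).
#' @return Tibble `pr_pat`, `pr_mat`, `side`, `prob`, `n_pat`, `n_mat`.
#' @export
prob_pofo_sib <- function(s_t, l_t, validation, window = 3) {
  w <- window
  repeat {
    sel <- validation[abs(validation$l - l_t) < w, ]
    if (sum(sel$parent_h0 == "pat") > 0 && sum(sel$parent_h0 == "mat") > 0) {
      break
    }
    w <- w + window
    if (w > max(abs(range(validation$l) - l_t)) + window) {
      stop("validation cohort lacks a truth class", call. = FALSE)
    }
  }
  if (w > window) {
    warning("empty score-calibration window; widened to +/-", w, " Morgans")
  }
  p <- prob_side_empirical(s_t, sel$s[sel$parent_h0 == "pat"],
                           sel$s[sel$parent_h0 == "mat"])
  tibble::tibble(pr_pat = p$pr_pat, pr_mat = p$pr_mat,
                 side = p$side, prob = p$prob,
                 n_pat = sum(sel$parent_h0 == "pat"),
                 n_mat = sum(sel$parent_h0 == "mat"))
}

#' Single-chromosome score assignment
#'
#' Without interchromosomal phasing each chromosome is assigned separately
#' with hard thresholds: `S_c < -2` calls haplotype 0 paternal, `S_c > 2`
#' maternal, otherwise undetermined.
#'
#' @param s_c Numeric vector of per-chromosome scores.
#' @return Character vector `"pat"`, `"mat"`, or `NA` (undetermined).
#' @export
single_chrom_assign <- function(s_c) {
  dplyr::case_when(s_c < -2 ~ "pat", s_c > 2 ~ "mat", TRUE ~ NA_character_)
}

#' Crossover scoring for one sibling pair
#'
#' Convenience pipeline: detect IBD between a target and one sibling across
#' chromosomes, call crossovers, apply the sex-map contrast and aggregate
#' scores.
#'
#' @param target_haps,sib_haps Named lists (chromosome -> `n_sites x 2`
#'   matrices).
#' @param map Genetic map tibble.
#' @param ... Passed to [detect_ibd()].
#' @return List with `calls`, `chrom_scores`, `s` (genome score) and `l`
#'   (total sex-averaged Morgans of the chromosomes analysed).
#' @export
sib_pair_score <- function(target_haps, sib_haps, map, ...) {
  segs <- purrr::imap(target_haps, function(H, ch) {
    detect_ibd(H, list(sib = sib_haps[[ch]]), map, chrom = ch,
               group = "SIB", ...)
  }) |>
    dplyr::bind_rows()
  calls <- crossover_delta(infer_crossovers(segs, map), map)
  cs <- chrom_scores(calls)
  lens <- map_lengths(map)
  list(calls = calls, chrom_scores = cs, s = genome_score(cs),
       l = sum(lens$l_c[lens$chrom %in% names(target_haps)]))
}
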