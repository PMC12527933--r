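#' Mitochondrial minor-variant sharing
#'
#' Proportion of shared minor alleles between two mtDNA minor-allele vectors:
#' `MVS(t, r) = (v_t . v_r) / M`. mtDNA is maternally inherited, so
#' maternal-line relatives share most minor alleles while paternal-line
#' relatives share only what segregates in the population.
#'
#' @param v_t,v_r Equal-length 0/1 vectors over the M mtDNA variants.
#' @return A fraction in `[0, 1]`.
#' @examples
#' mvs(c(1, 0, 1), c(1, 1, 1)) # 2/3
#' @export
mvs <- function(v_t, v_r) {
  stopifnot(length(v_t) == length(v_r))
  if (length(v_t) == 0) stop("MVS undefined for zero mtDNA variants",
                             call. = FALSE)
  sum(v_t * v_r) / length(v_t)
}

#' Build a parental-side calibration table
#'
#' Stores training observations of a predictor value (X sharing length in cM,
#' or mtDNA MVS) for targets whose relative's parental side is known, used by
#' [prob_side_x()] / [prob_side_mvs()] as the empirical reference
#' distributions. Values from several same-side relatives of one target
#' should be averaged before entry (one row per target and side).
#'
#' @param value Numeric predictor values.
#' @param side Truth sides, `"pat"` or `"mat"`.
#' @param stratum Optional stratum labels (e.g. relative degree `"2"`, `"3"`,
#'   `"4"` for MVS).
#' @return A tibble of class `pofo_calibration`.
#' @export
side_calibration <- function(value, side, stratum = NULL) {
  stopifnot(all(is.finite(value)), all(side %in% c("pat", "mat")))
  out <- tibble::tibble(value = value, side = side,
                        stratum = if (is.null(stratum)) "all" else
                          as.character(stratum))
  class(out) <- c("pofo_calibration", class(out))
  out
}

# Separation-maximising crossover between the "< l" (paternal) and "> l"
# (maternal) empirical estimators: the cut c maximising
# mean(pat < c) + mean(mat > c), taken at midpoints between consecutive
# pooled training values.
side_cut <- function(pat, mat) {
  v <- sort(unique(c(pat, mat)))
  if (length(v) == 1) return(v)
  cand <- (v[-1] + v[-length(v)]) / 2
  score <- vapply(cand, function(cc) mean(pat < cc) + mean(mat > cc), 0)
  # ties in the separation score are resolved to the centre of the
  # maximising candidates, keeping the cut in the middle of the class gap
  mean(cand[score == max(score)])
}

prob_side_empirical <- function(value, pat, mat) {
  if (length(pat) == 0 || length(mat) == 0) {
    stop("degenerate calibration: both truth classes are required",
         call. = FALSE)
  }
  # the "< l" form belongs to the class with the smaller typical value
  # (paternal on the X chromosome); orienting by the training means keeps
  # the estimator exactly symmetric under a pat/mat label exchange
  pat_low <- mean(pat) <= mean(mat)
  lo <- if (pat_low) pat else mat
  hi <- if (pat_low) mat else pat
  cut <- side_cut(lo, hi)
  one <- function(v) {
    if (v <= cut) {
      a <- mean(lo < v); b <- mean(hi < v)
      p <- if (a + b == 0) 0.5 else a / (a + b)
      pr_lo <- p
    } else {
      a <- mean(hi > v); b <- mean(lo > v)
      p <- if (a + b == 0) 0.5 else a / (a + b)
      pr_lo <- 1 - p
    }
    if (pat_low) c(pr_pat = pr_lo, pr_mat = 1 - pr_lo) else
      c(pr_pat = 1 - pr_lo, pr_mat = pr_lo)
  }
  res <- vapply(value, one, c(pr_pat = 0, pr_mat = 0))
  pr_pat <- unname(res["pr_pat", ])
  pr_mat <- unname(res["pr_mat", ])
  tibble::tibble(
    value = unname(value),
    pr_pat = pr_pat,
    pr_mat = pr_mat,
    side = ifelse(pr_pat >= pr_mat, "pat", "mat"),
    prob = pmax(pr_pat, pr_mat)
  )
}

#' Parental-side probability from X-chromosome sharing
#'
#' Empirical-ratio estimator on the training distributions of X sharing
#' lengths: for a query below the class-separating cut, the paternal
#' probability is `mean(l_pat < l) / (mean(l_pat < l) + mean(l_mat < l))`;
#' above the cut the symmetric "> l" maternal form is used. Indicators are
#' strict, matching the estimator's definition. A uniform prior over sides is
#' assumed.
#'
#' @param l Query sharing lengths in cM (`>= 0`), vectorised.
#' @param calibration A [side_calibration()] table for the X predictor.
#' @return Tibble `value`, `pr_pat`, `pr_mat`, `side`, `prob` (the winning
#'   side's probability, in `[0.5, 1]`; `pr_pat + pr_mat = 1`).
#' @examples
#' cal <- side_calibration(c(0, 1, 2, 12, 5, 30, 60, 90),
#'                         rep(c("pat", "mat"), each = 4))
#' prob_side_x(10, cal)$pr_pat # 0.75
#' @export
prob_side_x <- function(l, calibration) {
  stopifnot(all(l >= 0))
  prob_side_empirical(l, calibration$value[calibration$side == "pat"],
                      calibration$value[calibration$side == "mat"])
}

#' Parental-side probability from mtDNA minor-variant sharing
#'
#' The same empirical-ratio estimator as [prob_side_x()], applied to MVS
#' values within the stratum of the relative's degree: MVS distributions
#' differ strongly by degree (an intermediate male relative breaks the
#' maternal mtDNA line for distant relatives, so low MVS is only weakly
#' informative there, which the stratum's own training distribution
#' captures). Predictions for strata absent from the calibration are
#' withheld (`NA`).
#'
#' @param value Query MVS values, vectorised.
#' @param degree Relative degree per query (e.g. `2`, `3`, `4`).
#' @param calibration A stratified [side_calibration()] table.
#' @return As [prob_side_x()], with a `degree` column.
#' @export
prob_side_mvs <- function(value, degree, calibration) {
  degree <- rep_len(as.character(degree), length(value))
  out <- purrr::map2(value, degree, function(v, d) {
    cal <- calibration[calibration$stratum == d, ]
    if (nrow(cal) == 0 || length(unique(cal$side)) < 2) {
      return(tibble::tibble(value = v, pr_pat = NA_real_, pr_mat = NA_real_,
                            side = NA_character_, prob = NA_real_))
    }
    prob_side_empirical(v, cal$value[cal$side == "pat"],
                        cal$value[cal$side == "mat"])
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(degree = degree, .after = "value")
}

#' Leave-one-out side predictions over a calibration table
#'
#' Re-predicts each training observation with itself removed from the
#' calibration, the evaluation design used to assess the empirical-ratio
#' estimators without optimism.
#'
#' @param calibration A [side_calibration()] table.
#' @return Tibble with the held-out truth `side_truth` joined to the
#'   prediction columns.
#' @export
loo_side_predictions <- function(calibration) {
  purrr::map(seq_len(nrow(calibration)), function(i) {
    cal <- calibration[-i, ]
    cal <- cal[cal$stratum == calibration$stratum[i], ]
    if (length(unique(cal$side)) < 2) return(NULL)
    p <- prob_side_empirical(calibration$value[i],
                             cal$value[cal$side == "pat"],
                             cal$value[cal$side == "mat"])
    p$side_truth <- calibration$side[i]
    p$stratum <- calibration$stratum[i]
    p
  }) |>
    dplyr::bind_rows()
}

#' Accuracy of side calls above a probability threshold
#'
#' `TP / (TP + FP)` where TP are correct side calls with probability above
#' `p` and FP incorrect calls above `p`.
#'
#' @param predictions Tibble with `side` and `prob` columns.
#' @param truth Character vector of truth sides aligned with `predictions`.
#' @param p Probability threshold.
#' @return Accuracy in `[0, 1]`; `NA` (with a warning) when no call exceeds
#'   `p`.
#' @export
accuracy_at_threshold <- function(predictions, truth, p = 0.5) {
  keep <- !is.na(predictions$prob) & predictions$prob > p
  if (!any(keep)) {
    warning("no calls above probability ", p)
    return(NA_real_)
  }
  mean(predictions$side[keep] == truth[keep])
}
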