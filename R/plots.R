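#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan-style plot of an association scan
#'
#' Association strength (-log10 P) against genomic position, panelled by
#' chromosome, with optional significance lines.
#'
#' @param object A `pofo_assoc` tibble with `chrom` and `pos`.
#' @param thresholds Optional numeric vector of P-value thresholds drawn as
#'   horizontal lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pofo_assoc <- function(object, thresholds = NULL, ...) {
  d <- dplyr::filter(object, !is.na(.data$p))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos,
                                       y = -log10(.data$p))) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = expression(-log[10](italic(P))),
                  title = paste0(unique(d$mode), " scan")) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(thresholds),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Parental Z-score scatter with POE classification
#'
#' Paternal versus maternal Z-scores, coloured by the five-way POE class
#' (bipolar, maternal, maternal asymmetric, paternal, paternal asymmetric),
#' with the equality and zero lines.
#'
#' @param data Tibble with `z_pat` and `z_mat` columns (a `poe_class`
#'   column is used if present, otherwise computed).
#' @return A ggplot.
#' @export
plot_poe_classes <- function(data) {
  if (!"poe_class" %in% names(data)) {
    data$poe_class <- classify_poe(data$z_pat, data$z_mat)
  }
  ggplot2::ggplot(data, ggplot2::aes(x = .data$z_pat, y = .data$z_mat,
                                     colour = .data$poe_class)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70",
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70",
                        linetype = "dashed") +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red",
                         linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = expression(Z[Pat]), y = expression(Z[Mat]),
                  colour = "POE class") +
    ggplot2::theme_minimal()
}

#' Calibration plot for parental-side predictions
#'
#' Empirical accuracy of side calls within predicted-probability bins; a
#' well-calibrated predictor tracks the diagonal.
#'
#' @param predictions Tibble with `side`, `prob`.
#' @param truth Truth sides aligned with `predictions`.
#' @param breaks Probability bin edges.
#' @return A ggplot.
#' @export
plot_side_calibration <- function(predictions, truth,
                                  breaks = seq(0.5, 1, by = 0.1)) {
  d <- tibble::tibble(prob = predictions$prob,
                      correct = predictions$side == truth) |>
    dplyr::filter(!is.na(.data$prob)) |>
    dplyr::mutate(bin = cut(.data$prob, breaks, include.lowest = TRUE)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mid = mean(.data$prob), acc = mean(.data$correct),
                     n = dplyr::n(), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mid, y = .data$acc,
                                  size = .data$n)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60",
                         linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(xlim = c(0.5, 1), ylim = c(0.4, 1)) +
    ggplot2::labs(x = "predicted probability", y = "empirical accuracy") +
    ggplot2::theme_minimal()
}
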