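#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an association scan
#'
#' Broom-style view of a `pofo_assoc` result: one row per tested variant
#' with `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#'
#' @param x A `pofo_assoc` tibble from [assoc_scan()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pofo_assoc <- function(x, ...) {
  tibble::tibble(term = x$variant_id, estimate = x$beta,
                 std.error = x$se, statistic = x$beta / x$se,
                 p.value = x$p, mode = x$mode)
}

#' Glance at an association scan
#'
#' One-row summary: variants tested, minimum P, and the genomic-control
#' inflation factor (median chi-square over its null median).
#'
#' @param x A `pofo_assoc` tibble.
#' @param ... Unused.
#' @return A one-row tibble `n_variants`, `n_tested`, `min_p`, `lambda_gc`.
#' @export
glance.pofo_assoc <- function(x, ...) {
  z2 <- (x$beta / x$se)^2
  tibble::tibble(
    n_variants = nrow(x),
    n_tested = sum(!is.na(x$p)),
    min_p = suppressWarnings(min(x$p, na.rm = TRUE)),
    lambda_gc = stats::median(z2, na.rm = TRUE) / stats::qchisq(0.5, 1))
}

#' Glance at a simulated cohort
#'
#' @param x A `pofo_cohort`.
#' @param ... Unused.
#' @return One-row tibble of cohort dimensions.
#' @export
glance.pofo_cohort <- function(x, ...) {
  tibble::tibble(
    n_individuals = nrow(x$samples),
    n_genotyped = sum(x$samples$genotyped),
    n_families = length(unique(x$samples$family)),
    n_autosomes = length(x$haps),
    n_sites = sum(vapply(x$haps, nrow, 1L)),
    n_x_sites = if (is.null(x$x_haps)) 0L else nrow(x$x_haps),
    n_mt_sites = if (is.null(x$mt)) 0L else nrow(x$mt))
}
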