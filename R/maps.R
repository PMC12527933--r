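#' Simulate sex-specific genetic maps
#'
#' Generates a marker grid per chromosome together with cumulative female and
#' male genetic positions. Per-interval centimorgan increments combine a
#' fine-scale hotspot intensity shared between the sexes (gamma distributed
#' per interval) with smooth, independent sex-specific log-rate fields, then
#' rescale to the requested chromosome totals. This mirrors real pedigree
#' maps: hotspots are largely shared, but the female/male rate ratio varies
#' on a broad spatial scale (for example male recombination concentrating
#' towards telomeres), so the local sex contrast is spatially coherent - the
#' property that makes crossover parental-origin scoring robust to
#' marker-level breakend placement.
#'
#' @param n_chrom Number of autosomes.
#' @param n_sites Markers per autosome (recycled).
#' @param bp_length Physical length of each autosome in bp (recycled).
#' @param cm_female,cm_male Total female/male genetic length per autosome in
#'   centimorgans (recycled across chromosomes).
#' @param shape Gamma shape of the shared fine-scale hotspot intensity;
#'   smaller is spikier.
#' @param smooth_knots Number of spline knots of each sex-specific log-rate
#'   field per chromosome.
#' @param smooth_sd Standard deviation of the knot values (log scale);
#'   controls how strongly the female/male ratio varies along a chromosome.
#' @param include_x Also emit an X-chromosome map (female recombination only;
#'   the male column is set equal to the female one so that sex-averaged
#'   lengths coincide with the female map).
#' @param x_sites,x_bp_length,x_cm Marker count, physical and genetic length
#'   of the X map.
#' @return A tibble with columns `chrom`, `pos`, `cm_female`, `cm_male`;
#'   positions strictly increasing and cM columns non-decreasing per
#'   chromosome. Autosomes are named `"1"`, `"2"`, ... and the X `"X"`.
#' @examples
#' map <- sim_genetic_map(n_chrom = 2, n_sites = 100)
#' map_lengths(map)
#' @export
sim_genetic_map <- function(n_chrom = 6, n_sites = 600, bp_length = 1e8,
                            cm_female = 195, cm_male = 118, shape = 0.3,
                            smooth_knots = 10, smooth_sd = 1,
                            include_x = FALSE, x_sites = 300,
                            x_bp_length = 1.5e8, x_cm = 180) {
  stopifnot(n_chrom >= 1, all(n_sites > 1))
  n_sites <- rep_len(n_sites, n_chrom)
  bp_length <- rep_len(bp_length, n_chrom)
  cm_female <- rep_len(cm_female, n_chrom)
  cm_male <- rep_len(cm_male, n_chrom)
  smooth_field <- function(x) {
    kx <- seq(min(x), max(x), length.out = smooth_knots)
    ky <- stats::rnorm(smooth_knots, 0, smooth_sd)
    stats::spline(kx, ky, xout = x)$y
  }
  one_chrom <- function(ns, bp, cmf, cmm, name) {
    pos <- sort(sample.int(bp - 1L, ns))
    mid <- (pos[-1] + pos[-ns]) / 2
    hot <- stats::rgamma(ns - 1L, shape = shape) # shared hotspot intensity
    incf <- hot * exp(smooth_field(mid))
    incm <- hot * exp(smooth_field(mid))
    tibble::tibble(
      chrom = name,
      pos = pos,
      cm_female = c(0, cumsum(incf)) / max(sum(incf), 1e-12) * cmf,
      cm_male = c(0, cumsum(incm)) / max(sum(incm), 1e-12) * cmm
    )
  }
  out <- purrr::pmap(
    list(n_sites, bp_length, cm_female, cm_male, as.character(seq_len(n_chrom))),
    one_chrom
  )
  if (include_x) {
    x <- one_chrom(x_sites, x_bp_length, x_cm, x_cm, "X")
    x$cm_male <- x$cm_female
    out <- c(out, list(x))
  }
  dplyr::bind_rows(out)
}

#' Genetic map lengths per chromosome
#'
#' @param map A genetic map tibble (`chrom`, `pos`, `cm_female`, `cm_male`).
#' @return A tibble with per-chromosome total cM per sex and lengths in
#'   Morgans, including the sex-averaged length `l_c` used for expected
#'   crossover counts (lambda = 4 l_c in sibling pairs).
#' @export
map_lengths <- function(map) {
  map |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      cm_female = max(.data$cm_female) - min(.data$cm_female),
      cm_male = max(.data$cm_male) - min(.data$cm_male),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      morgans_female = .data$cm_female / 100,
      morgans_male = .data$cm_male / 100,
      l_c = (.data$morgans_female + .data$morgans_male) / 2
    )
}

#' Interpolate genetic positions
#'
#' Linear interpolation of the female and male cM coordinates at arbitrary
#' base-pair positions on one chromosome. Positions outside the map range are
#' clamped to the terminal map values.
#'
#' @param map Genetic map tibble.
#' @param chrom Chromosome identifier (single value).
#' @param bp Numeric vector of base-pair positions.
#' @return A tibble with columns `bp`, `cm_female`, `cm_male` (and `cm_avg`,
#'   the sex-averaged coordinate).
#' @examples
#' map <- sim_genetic_map(n_chrom = 1, n_sites = 50)
#' interpolate_cm(map, "1", c(1e6, 5e7))
#' @export
interpolate_cm <- function(map, chrom, bp) {
  m <- map[map$chrom == chrom, ]
  if (nrow(m) == 0) {
    stop("chromosome '", chrom, "' not present in map", call. = FALSE)
  }
  cf <- stats::approx(m$pos, m$cm_female, xout = bp, rule = 2)$y
  cm <- stats::approx(m$pos, m$cm_male, xout = bp, rule = 2)$y
  tibble::tibble(bp = bp, cm_female = cf, cm_male = cm,
                 cm_avg = (cf + cm) / 2)
}
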