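#' Rank-based inverse-normal transform
#'
#' Maps a numeric vector to standard-normal quantiles via
#' `qnorm((rank - 0.5) / n)`, ties mid-ranked; `NA`s are preserved.
#'
#' @param x Numeric vector.
#' @return Transformed vector.
#' @export
int_transform <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  out[ok] <- stats::qnorm((rank(x[ok], ties.method = "average") - 0.5) / n)
  out
}

#' Prepare a phenotype for association scanning
#'
#' Quantitative traits: per-individual values are averaged across available
#' time points, then inverse-normal transformed. Binary traits: individuals
#' carrying any inclusion code become cases; individuals carrying any
#' exclusion code are removed from cases and controls; the remaining `ids`
#' are controls.
#'
#' @param records For quantitative traits a tibble `iid`, `value` (multiple
#'   rows per individual allowed); for binary traits a tibble `iid`, `code`.
#' @param kind `"quantitative"` or `"binary"`.
#' @param include_codes,exclude_codes Code sets defining binary cases and
#'   exclusions.
#' @param ids Universe of individuals for binary traits (controls are the
#'   non-case, non-excluded members).
#' @return Tibble `iid`, `y`.
#' @export
prep_phenotype <- function(records, kind = c("quantitative", "binary"),
                           include_codes = NULL, exclude_codes = NULL,
                           ids = NULL) {
  kind <- match.arg(kind)
  if (kind == "quantitative") {
    records |>
      dplyr::group_by(iid = .data$iid) |>
      dplyr::summarise(y = mean(.data$value, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::filter(is.finite(.data$y)) |>
      dplyr::mutate(y = int_transform(.data$y))
  } else {
    stopifnot(!is.null(include_codes), !is.null(ids))
    cases <- unique(records$iid[records$code %in% include_codes])
    excl <- if (is.null(exclude_codes)) character(0) else
      unique(records$iid[records$code %in% exclude_codes])
    tibble::tibble(iid = setdiff(ids, excl)) |>
      dplyr::mutate(y = as.integer(.data$iid %in% setdiff(cases, excl)))
  }
}

# OLS slope/se/p for the last column of X; returns c(beta, se, p, n).
ols_fit <- function(X, y) {
  ok <- stats::complete.cases(X, y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y); p <- ncol(X)
  if (n <= p || stats::var(X[, p]) == 0) {
    return(c(NA_real_, NA_real_, NA_real_, n))
  }
  qx <- qr(X)
  if (qx$rank < p) return(c(NA_real_, NA_real_, NA_real_, n))
  cf <- qr.coef(qx, y)
  res <- y - X %*% cf
  s2 <- sum(res^2) / (n - p)
  xtxi <- chol2inv(qr.R(qx))
  se <- sqrt(s2 * xtxi[p, p])
  tval <- cf[p] / se
  c(cf[p], se, 2 * stats::pt(abs(tval), n - p, lower.tail = FALSE), n)
}

logit_fit <- function(X, y) {
  ok <- stats::complete.cases(X, y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y); p <- ncol(X)
  if (n <= p || stats::var(X[, p]) == 0) {
    return(c(NA_real_, NA_real_, NA_real_, n))
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  beta <- fit$coefficients[p]
  # separation: runaway estimate or failed convergence
  if (!fit$converged || is.na(beta) || abs(beta) > 15) {
    return(c(beta, NA_real_, NA_real_, n))
  }
  W <- fit$weights
  xtwxi <- tryCatch(chol2inv(chol(crossprod(X * sqrt(W)))),
                    error = function(e) NULL)
  if (is.null(xtwxi)) return(c(beta, NA_real_, NA_real_, n))
  se <- sqrt(xtwxi[p, p])
  z <- beta / se
  c(beta, se, 2 * stats::pnorm(abs(z), lower.tail = FALSE), n)
}

#' Parent-of-origin association scans
#'
#' Per-variant regression of a prepared phenotype on the mode's regressor:
#' diploid dosage `DS_dip` (`"add"`), paternal dosage `DS_pat` (`"pat"`),
#' maternal dosage `DS_mat` (`"mat"`), or, for the differential scan
#' (`"diff"`), the paternal fraction `DS_pat / DS_dip` over heterozygous
#' entries passing the parental-dosage certainty filter - the direct test of
#' paternal versus maternal effect equality. Quantitative traits use least
#' squares, binary traits logistic maximum likelihood (separation is flagged
#' and the P value withheld). Variants failing `keep_variant` are skipped.
#'
#' @param encoding A [pofo_encoding()], optionally after [filter_variants()].
#' @param phenotype Tibble `iid`, `y`.
#' @param covariates Optional tibble with `iid` and numeric covariate
#'   columns.
#' @param mode One of `"add"`, `"pat"`, `"mat"`, `"diff"`.
#' @param kind `"quantitative"` or `"binary"`.
#' @return A `pofo_assoc` tibble: `variant_id`, `mode`, `n`, `beta`, `se`,
#'   `p`, joined with any `chrom`/`pos`/`maf` variant metadata.
#' @export
assoc_scan <- function(encoding, phenotype, covariates = NULL,
                       mode = c("add", "pat", "mat", "diff"),
                       kind = c("quantitative", "binary")) {
  mode <- match.arg(mode)
  kind <- match.arg(kind)
  stopifnot(inherits(encoding, "pofo_encoding"))
  iid <- encoding$iid
  y <- phenotype$y[match(iid, phenotype$iid)]
  C <- matrix(1, length(iid), 1)
  if (!is.null(covariates)) {
    cc <- covariates[match(iid, covariates$iid), , drop = FALSE]
    C <- cbind(C, as.matrix(cc[setdiff(names(cc), "iid")]))
  }
  G <- switch(mode,
    add = encoding$ds_dip,
    pat = encoding$ds_pat,
    mat = encoding$ds_mat,
    diff = {
      g <- encoding$ds_pat / encoding$ds_dip
      g[!encoding$het | encoding$ds_dip == 0] <- NA
      if (!is.null(encoding$diff_ok)) g[!encoding$diff_ok] <- NA
      g
    })
  keep <- which(encoding$keep_variant)
  fit_fun <- if (kind == "quantitative") ols_fit else logit_fit
  res <- matrix(NA_real_, ncol(G), 4)
  for (j in keep) {
    res[j, ] <- fit_fun(cbind(C, G[, j]), y)
  }
  out <- tibble::tibble(
    variant_id = colnames(G), mode = mode,
    n = as.integer(res[, 4]), beta = res[, 1], se = res[, 2], p = res[, 3])
  meta <- encoding$variants[, intersect(names(encoding$variants),
                                        c("variant_id", "chrom", "pos",
                                          "maf", "info")), drop = FALSE]
  out <- dplyr::left_join(out, meta, by = "variant_id")
  class(out) <- c("pofo_assoc", class(out))
  attr(out, "kind") <- kind
  out
}

#' Differential parent-of-origin Z test from summary statistics
#'
#' `Z_D = (beta_P - beta_M) / sqrt(se_P^2 + se_M^2)`,
#' `P_D = 2 (1 - Phi(|Z_D|))` - the standardised contrast of paternal and
#' maternal effect estimates, used to impose one differential standard on
#' studies reporting only parent-specific coefficients.
#'
#' @param beta_p,se_p,beta_m,se_m Paternal/maternal estimates and standard
#'   errors (vectorised; `se > 0` required).
#' @return Tibble `z_d`, `p_d`.
#' @export
differential_z <- function(beta_p, se_p, beta_m, se_m) {
  stopifnot(all(se_p > 0), all(se_m > 0))
  z <- (beta_p - beta_m) / sqrt(se_p^2 + se_m^2)
  tibble::tibble(z_d = z, p_d = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Classify a parent-of-origin effect pattern
#'
#' Five-way classification from the paternal and maternal Z-scores:
#' `bipolar` (opposite signs, comparable magnitudes: each above half the
#' other), `maternal` (`|Z_Pat| < 0.5 |Z_Mat|`), `paternal` (symmetric),
#' `maternal_asymmetric` (same sign, maternal dominant but paternal still
#' above half), `paternal_asymmetric` (symmetric). Parent-dominant rules are
#' evaluated before the asymmetric rules; an exact magnitude tie with equal
#' signs classifies as maternal asymmetric. Zero or non-finite Z-scores are
#' unclassified (`NA`).
#'
#' @param z_pat,z_mat Numeric vectors of Z-scores.
#' @return Factor with levels `bipolar`, `maternal`, `maternal_asymmetric`,
#'   `paternal`, `paternal_asymmetric`.
#' @examples
#' classify_poe(-5.0, 3.4)  # bipolar
#' classify_poe(-15.25, -8.5) # paternal_asymmetric
#' @export
classify_poe <- function(z_pat, z_mat) {
  ap <- abs(z_pat); am <- abs(z_mat)
  lab <- dplyr::case_when(
    !is.finite(z_pat) | !is.finite(z_mat) | z_pat == 0 | z_mat == 0 ~
      NA_character_,
    ap < 0.5 * am ~ "maternal",
    am < 0.5 * ap ~ "paternal",
    sign(z_pat) != sign(z_mat) ~ "bipolar",
    am >= ap ~ "maternal_asymmetric",
    TRUE ~ "paternal_asymmetric")
  factor(lab, levels = c("bipolar", "maternal", "maternal_asymmetric",
                         "paternal", "paternal_asymmetric"))
}

#' Effective number of tests from a correlation matrix
#'
#' The simpleM rule: the smallest k such that the top-k eigenvalues of the
#' (symmetrised) correlation matrix explain at least `threshold` of the
#' total variance.
#'
#' @param R Correlation matrix (symmetric positive semi-definite up to
#'   numerical tolerance).
#' @param threshold Variance-explained cutoff (default 0.995).
#' @return Integer effective test count.
#' @export
n_eff <- function(R, threshold = 0.995) {
  R <- (R + t(R)) / 2
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("matrix is not positive semi-definite", call. = FALSE)
  }
  ev <- pmax(ev, 0)
  which(cumsum(ev) / sum(ev) >= threshold)[1]
}

#' Significance thresholds for POE scans
#'
#' Genome-wide: `5e-8 / N_eff(traits)`. Additive-region focus:
#' `0.05 / N_a` for `N_a` independent additive associations.
#' Imprinted-region focus: suggestive at `0.05 / N_tests`, significant at
#' the suggestive level divided by `N_eff(traits)`.
#'
#' @param n_eff_traits Effective number of traits (e.g. 48).
#' @param n_additive Number of independent additive associations.
#' @param n_imprinted_tests Number of independent tests within imprinted
#'   regions.
#' @return Tibble `threshold`, `value`.
#' @examples
#' poe_thresholds(48, n_imprinted_tests = 16574)
#' @export
poe_thresholds <- function(n_eff_traits, n_additive = NULL,
                           n_imprinted_tests = NULL) {
  stopifnot(n_eff_traits > 0)
  sugg <- if (is.null(n_imprinted_tests)) NA_real_ else
    0.05 / n_imprinted_tests
  tibble::tibble(
    threshold = c("genome_wide", "additive_region",
                  "imprinted_suggestive", "imprinted_significant"),
    value = c(5e-8 / n_eff_traits,
              if (is.null(n_additive)) NA_real_ else 0.05 / n_additive,
              sugg, sugg / n_eff_traits))
}

#' Greedy pruning to independent hits
#'
#' Keeps the smallest-P hit and removes neighbours within `window_bp` or in
#' linkage disequilibrium (`r^2` at or above `r2_max`), repeating until no
#' hit remains unassessed.
#'
#' @param results Tibble with `variant_id`, `chrom`, `pos`, `p`.
#' @param genotypes Optional dosage matrix (individuals x variants, columns
#'   named by `variant_id`) for the r-squared computation; without it only
#'   the distance rule applies.
#' @param window_bp Distance window (default 5e5).
#' @param r2_max LD threshold (default 0.01).
#' @return The retained rows of `results`.
#' @export
prune_hits <- function(results, genotypes = NULL, window_bp = 5e5,
                       r2_max = 0.01) {
  d <- results[order(results$p), ]
  kept <- d[0, ]
  while (nrow(d) > 0) {
    lead <- d[1, ]
    kept <- dplyr::bind_rows(kept, lead)
    near <- d$chrom == lead$chrom & abs(d$pos - lead$pos) < window_bp
    if (!is.null(genotypes)) {
      r2 <- rep(0, nrow(d))
      same <- d$chrom == lead$chrom
      if (any(same)) {
        r2[same] <- suppressWarnings(
          stats::cor(genotypes[, lead$variant_id],
                     genotypes[, d$variant_id[same], drop = FALSE]))^2
      }
      near <- near | (!is.na(r2) & r2 >= r2_max)
    }
    d <- d[!near & d$variant_id != lead$variant_id, ]
  }
  kept
}

#' Conditional differential scan
#'
#' Repeats a scan with the lead variant appended to the covariates, yielding
#' conditional P values for secondary-signal discovery. The covariate is the
#' lead's regressor for the same scan mode: for the differential scan this is
#' its paternal fraction over heterozygous entries — an additive dosage
#' covariate could not absorb a parental-origin signal, so linkage proxies
#' would never null out. Variants collinear with the lead (including the
#' lead itself) are flagged (`collinear`) with P withheld.
#'
#' @param encoding A [pofo_encoding()].
#' @param phenotype,covariates,mode,kind As in [assoc_scan()].
#' @param lead_variant Variant id to condition on.
#' @return A `pofo_assoc` tibble with a `collinear` column.
#' @export
conditional_scan <- function(encoding, phenotype, covariates = NULL,
                             lead_variant, mode = "diff",
                             kind = "quantitative") {
  stopifnot(lead_variant %in% colnames(encoding$ds_dip))
  mode_regressor <- function(j) {
    switch(mode,
      add = encoding$ds_dip[, j],
      pat = encoding$ds_pat[, j],
      mat = encoding$ds_mat[, j],
      diff = {
        g <- encoding$ds_pat[, j] / encoding$ds_dip[, j]
        g[!encoding$het[, j] | encoding$ds_dip[, j] == 0] <- NA
        g
      })
  }
  lead_g <- mode_regressor(lead_variant)
  lead <- tibble::tibble(iid = encoding$iid, lead_g = lead_g)
  covariates <- if (is.null(covariates)) lead else
    dplyr::left_join(covariates, lead, by = "iid")
  out <- assoc_scan(encoding, phenotype, covariates, mode = mode, kind = kind)
  r <- vapply(colnames(encoding$ds_dip), function(j) {
    suppressWarnings(stats::cor(lead_g, mode_regressor(j),
                                use = "pairwise.complete.obs"))
  }, 0)
  out$collinear <- is.na(r) | abs(r) > 0.999
  out$p[out$collinear] <- NA_real_
  out
}

#' Sex-difference Z test for differential effects
#'
#' `Z = (betaD_males - betaD_females) / sqrt(se_m^2 + se_f^2)` with a
#' two-sided normal P value, contrasting differential-scan coefficients
#' estimated separately per sex.
#'
#' @param beta_d_males,se_d_males,beta_d_females,se_d_females Sex-specific
#'   differential estimates (`se > 0`).
#' @return Tibble `z`, `p`.
#' @export
sex_diff_z <- function(beta_d_males, se_d_males, beta_d_females,
                       se_d_females) {
  stopifnot(all(se_d_males > 0), all(se_d_females > 0))
  z <- (beta_d_males - beta_d_females) /
    sqrt(se_d_males^2 + se_d_females^2)
  tibble::tibble(z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Ratio of parent-specific odds ratios
#'
#' From parent-specific odds ratios with 95% confidence intervals, computes
#' the odds ratio of carrying the allele paternally versus maternally:
#' per-parent log-OR standard errors are recovered as
#' `(log U - log L) / (2 * 1.96)` and combined on the log scale.
#'
#' @param or_pat,or_mat Odds ratios (`> 0`).
#' @param ci_pat,ci_mat Length-2 vectors `(lower, upper)` of the 95% CIs.
#' @return Tibble `ratio`, `lower`, `upper`.
#' @examples
#' or_ratio(1.14, c(1.08, 1.21), 0.91, c(0.86, 0.96))
#' @export
or_ratio <- function(or_pat, ci_pat, or_mat, ci_mat) {
  stopifnot(or_pat > 0, or_mat > 0, all(ci_pat > 0), all(ci_mat > 0))
  if (ci_pat[1] >= ci_pat[2] || ci_mat[1] >= ci_mat[2]) {
    stop("confidence interval bounds are inverted", call. = FALSE)
  }
  se_p <- (log(ci_pat[2]) - log(ci_pat[1])) / (2 * 1.96)
  se_m <- (log(ci_mat[2]) - log(ci_mat[1])) / (2 * 1.96)
  d <- log(or_pat) - log(or_mat)
  hw <- 1.96 * sqrt(se_p^2 + se_m^2)
  tibble::tibble(ratio = exp(d), lower = exp(d - hw), upper = exp(d + hw))
}

#' Z test for a difference of heritability estimates
#'
#' `Z = (h2_a - h2_b) / sqrt(se_a^2 + se_b^2)` with a two-sided normal P.
#' Subset estimates (e.g. within versus outside imprinted regions) should be
#' pre-weighted by the proportion of variants in the subset before entry.
#'
#' @param h2_a,se_a,h2_b,se_b Heritability estimates and standard errors
#'   (`se > 0`).
#' @return Tibble `z`, `p`.
#' @export
h2_diff_z <- function(h2_a, se_a, h2_b, se_b) {
  stopifnot(all(se_a > 0), all(se_b > 0))
  z <- (h2_a - h2_b) / sqrt(se_a^2 + se_b^2)
  tibble::tibble(z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}
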