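#' Simulation configuration
#'
#' Bundles all knobs of the cohort simulator. Defaults describe the study
#' conditions used throughout the package's validation suites: a mixture of
#' family configurations (trios, duos, sibling pairs, and families carrying a
#' 2nd/3rd/4th-degree surrogate-parent relative), array-like genotyping error,
#' statistical-phasing-like switch error, and mtDNA transmitted maternally
#' with a small per-meiosis flip rate plus call noise.
#'
#' @param n_families Number of independent families.
#' @param family_mix Named proportions over
#'   `c("trio","duo","sibling","second","third","fourth")`; must sum to 1.
#' @param map Optional genetic map tibble; if `NULL` one is simulated from
#'   `map_args`.
#' @param map_args List of arguments for [sim_genetic_map()].
#' @param maf_shape1,maf_shape2 Beta parameters of the founder allele-frequency
#'   spectrum (truncated to `[0.05, 0.95]` so every site is informative).
#' @param genotype_error Per-allele flip probability in the observed data.
#' @param switch_error Phase switch rate per centimorgan in observed
#'   haplotypes (a Poisson process along the sex-averaged map).
#' @param mt_sites Number of mtDNA variant sites.
#' @param mt_mutation_rate Per-site flip probability per meiosis on mtDNA.
#' @param mt_noise Per-site mtDNA call-noise flip probability per individual.
#' @param both_sides Probability that a distant-relative family carries a
#'   surrogate relative on both parental sides rather than one.
#' @param seed Integer seed; the whole cohort is reproducible bit-for-bit.
#' @return A list of class `pofo_sim_config`.
#' @export
sim_config <- function(n_families = 50,
                       family_mix = c(trio = 0.2, duo = 0.1, sibling = 0.2,
                                      second = 0.2, third = 0.15, fourth = 0.15),
                       map = NULL,
                       map_args = list(n_chrom = 6, n_sites = 600,
                                       include_x = TRUE),
                       maf_shape1 = 0.8, maf_shape2 = 0.8,
                       genotype_error = 1e-3, switch_error = 0.005,
                       mt_sites = 300, mt_mutation_rate = 0.002,
                       mt_noise = 0.002, both_sides = 0.5, seed = 1L) {
  stopifnot(n_families >= 1, all(family_mix >= 0), all(family_mix <= 1))
  if (abs(sum(family_mix) - 1) > 1e-8) {
    stop("family_mix proportions must sum to 1", call. = FALSE)
  }
  stopifnot(genotype_error >= 0, genotype_error < 1,
            switch_error >= 0, mt_sites >= 0)
  structure(
    list(n_families = n_families, family_mix = family_mix, map = map,
         map_args = map_args, maf_shape1 = maf_shape1, maf_shape2 = maf_shape2,
         genotype_error = genotype_error, switch_error = switch_error,
         mt_sites = mt_sites, mt_mutation_rate = mt_mutation_rate,
         mt_noise = mt_noise, both_sides = both_sides, seed = as.integer(seed)),
    class = "pofo_sim_config"
  )
}

#' Simulate one meiosis
#'
#' Draws a Poisson number of crossovers with mean equal to the transmitting
#' parent's sex-specific map length in Morgans, places them i.i.d. on that
#' sex's cM scale (mapped back to bp by inverse interpolation), and builds the
#' gamete as an alternating mosaic of the parent's two haplotypes. No
#' crossover interference is modelled.
#'
#' @param parent_haps Integer matrix `n_sites x 2`: the parent's haplotypes
#'   over the map grid of one chromosome.
#' @param sex `"male"` or `"female"`: which map scale governs recombination.
#' @param map Genetic map tibble.
#' @param chrom Chromosome to simulate on.
#' @return A list with `gamete` (integer vector) and `crossovers` (numeric bp
#'   positions, strictly increasing).
#' @examples
#' map <- sim_genetic_map(n_chrom = 1, n_sites = 200)
#' haps <- cbind(rep(0L, 200), rep(1L, 200))
#' simulate_meiosis(haps, "male", map, "1")$crossovers
#' @export
simulate_meiosis <- function(parent_haps, sex = c("male", "female"), map, chrom) {
  sex <- match.arg(sex)
  m <- map[map$chrom == chrom, ]
  if (nrow(m) == 0) stop("empty map for chromosome ", chrom, call. = FALSE)
  stopifnot(is.matrix(parent_haps), ncol(parent_haps) == 2,
            nrow(parent_haps) == nrow(m))
  cm <- if (sex == "male") m$cm_male else m$cm_female
  total <- max(cm) - min(cm)
  n_co <- if (total <= 0) 0L else stats::rpois(1L, total / 100)
  start <- sample.int(2L, 1L)
  if (n_co == 0L) {
    return(list(gamete = parent_haps[, start], crossovers = numeric(0),
                start = start))
  }
  u <- sort(stats::runif(n_co, min(cm), max(cm)))
  bp <- stats::approx(cm, m$pos, xout = u, ties = "ordered", rule = 2)$y
  bp <- sort(bp)
  k <- findInterval(m$pos, bp)
  idx <- (start - 1L + k) %% 2L + 1L
  list(gamete = parent_haps[cbind(seq_len(nrow(m)), idx)], crossovers = bp,
       start = start)
}

# Family pedigree templates. Local ids; father/mother NA for founders.
# role marks what downstream stages may use the individual for.
family_template <- function(type, both_sides) {
  ped <- function(id, sex, father, mother, gen, genotyped, role) {
    tibble::tibble(id = id, sex = sex, father = father, mother = mother,
                   gen = gen, genotyped = genotyped, role = role)
  }
  rsex <- function() sample(c(1L, 2L), 1L)
  sides <- tibble::tibble(target = character(), relative = character(),
                          side = character(), degree = integer())
  sibs <- tibble::tibble(iid_a = character(), iid_b = character())
  if (type == "trio") {
    p <- dplyr::bind_rows(
      ped("fa", 1L, NA, NA, 1L, TRUE, "father"),
      ped("mo", 2L, NA, NA, 1L, TRUE, "mother"),
      ped("t", rsex(), "fa", "mo", 2L, TRUE, "target"))
    sides <- tibble::tibble(target = "t", relative = c("fa", "mo"),
                            side = c("pat", "mat"), degree = 1L)
  } else if (type == "duo") {
    keep <- sample(c("fa", "mo"), 1L)
    p <- dplyr::bind_rows(
      ped("fa", 1L, NA, NA, 1L, keep == "fa", "father"),
      ped("mo", 2L, NA, NA, 1L, keep == "mo", "mother"),
      ped("t", rsex(), "fa", "mo", 2L, TRUE, "target"))
    sides <- tibble::tibble(target = "t", relative = keep,
                            side = if (keep == "fa") "pat" else "mat",
                            degree = 1L)
  } else if (type == "sibling") {
    p <- dplyr::bind_rows(
      ped("fa", 1L, NA, NA, 1L, FALSE, "father"),
      ped("mo", 2L, NA, NA, 1L, FALSE, "mother"),
      ped("s1", rsex(), "fa", "mo", 2L, TRUE, "target"),
      ped("s2", rsex(), "fa", "mo", 2L, TRUE, "sibling"))
    sibs <- tibble::tibble(iid_a = "s1", iid_b = "s2")
  } else {
    # distant-relative families share a common scaffold: four ungenotyped
    # grandparents, ungenotyped parents, genotyped target; the surrogate
    # relative hangs off one (or both) grandparental couples.
    p <- dplyr::bind_rows(
      ped("gf_p", 1L, NA, NA, 0L, FALSE, "ancestor"),
      ped("gm_p", 2L, NA, NA, 0L, FALSE, "ancestor"),
      ped("gf_m", 1L, NA, NA, 0L, FALSE, "ancestor"),
      ped("gm_m", 2L, NA, NA, 0L, FALSE, "ancestor"),
      ped("fa", 1L, "gf_p", "gm_p", 1L, FALSE, "father"),
      ped("mo", 2L, "gf_m", "gm_m", 1L, FALSE, "mother"),
      ped("t", rsex(), "fa", "mo", 2L, TRUE, "target"))
    use_sides <- if (stats::runif(1) < both_sides) c("pat", "mat") else {
      sample(c("pat", "mat"), 1L)
    }
    for (sd in use_sides) {
      gp <- if (sd == "pat") c("gf_p", "gm_p") else c("gf_m", "gm_m")
      unc <- paste0("unc_", sd)
      p <- dplyr::bind_rows(p,
        ped(unc, rsex(), gp[1], gp[2], 1L, type == "second", "relative"))
      rel <- unc
      deg <- 2L
      if (type %in% c("third", "fourth")) {
        sp1 <- paste0("sp1_", sd)
        cou <- paste0("cou_", sd)
        p <- dplyr::bind_rows(p,
          ped(sp1, 3L - p$sex[p$id == unc], NA, NA, 1L, FALSE, "ancestor"),
          ped(cou, rsex(), if (p$sex[p$id == unc] == 1L) unc else sp1,
              if (p$sex[p$id == unc] == 1L) sp1 else unc,
              2L, type == "third", "relative"))
        rel <- cou
        deg <- 3L
      }
      if (type == "fourth") {
        cou <- paste0("cou_", sd)
        sp2 <- paste0("sp2_", sd)
        cc <- paste0("cc_", sd)
        p <- dplyr::bind_rows(p,
          ped(sp2, 3L - p$sex[p$id == cou], NA, NA, 2L, FALSE, "ancestor"),
          ped(cc, rsex(), if (p$sex[p$id == cou] == 1L) cou else sp2,
              if (p$sex[p$id == cou] == 1L) sp2 else cou,
              3L, TRUE, "relative"))
        rel <- cc
        deg <- 4L
      }
      sides <- dplyr::bind_rows(sides,
        tibble::tibble(target = "t", relative = rel, side = sd, degree = deg))
    }
  }
  list(ped = p, sides = sides, sibs = sibs)
}

#' Simulate a cohort with full ground truth
#'
#' Realises the configured family mixture by repeated [simulate_meiosis()]
#' calls under sex-specific maps, records the truth pedigree, parent-of-origin
#' of every haplotype (index 0 paternal, index 1 maternal), crossover
#' positions per meiosis, X-chromosome inheritance (males carry a single,
#' maternal X), and maternally transmitted mtDNA minor-allele vectors. The
#' observed data (`$obs`) are a corrupted copy produced by [corrupt_cohort()]
#' using the configured error rates; truth is retained separately.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `pofo_cohort` with elements `map`, `samples`,
#'   `pedigree`, `haps` (truth, per chromosome: `n_sites x 2N` integer matrix,
#'   columns `<iid>|0` = paternal, `<iid>|1` = maternal), `obs` (same shape),
#'   `x_haps` (males: column `<iid>|0` is `NA`), `mt` (sites x N), `freqs`,
#'   `sides` (truth surrogate-relative sides), `sib_pairs`, `crossovers`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "pofo_sim_config"))
  set.seed(config$seed)
  map <- config$map %||%
    do.call(sim_genetic_map, config$map_args)
  chroms <- setdiff(unique(map$chrom), "X")
  has_x <- "X" %in% map$chrom

  types <- sample(names(config$family_mix), config$n_families, replace = TRUE,
                  prob = config$family_mix)
  fams <- purrr::imap(types, function(tp, i) {
    fm <- family_template(tp, config$both_sides)
    pre <- sprintf("F%03d_", i)
    fm$ped$id <- paste0(pre, fm$ped$id)
    fm$ped$father <- ifelse(is.na(fm$ped$father), NA, paste0(pre, fm$ped$father))
    fm$ped$mother <- ifelse(is.na(fm$ped$mother), NA, paste0(pre, fm$ped$mother))
    fm$ped$family <- sprintf("F%03d", i)
    fm$ped$type <- tp
    if (nrow(fm$sides)) {
      fm$sides$target <- paste0(pre, fm$sides$target)
      fm$sides$relative <- paste0(pre, fm$sides$relative)
    }
    if (nrow(fm$sibs)) {
      fm$sibs$iid_a <- paste0(pre, fm$sibs$iid_a)
      fm$sibs$iid_b <- paste0(pre, fm$sibs$iid_b)
    }
    fm
  })
  ped <- dplyr::bind_rows(purrr::map(fams, "ped"))
  sides <- dplyr::bind_rows(purrr::map(fams, "sides"))
  sibs <- dplyr::bind_rows(purrr::map(fams, "sibs"))

  # generation-consistent ages: parents are ~28 years older than offspring
  ped$age <- round(85 - 28 * ped$gen + stats::rnorm(nrow(ped), 0, 3))
  ped <- ped[order(ped$gen), ]
  n <- nrow(ped)
  iid <- ped$id
  fa_idx <- match(ped$father, iid)
  mo_idx <- match(ped$mother, iid)

  freqs <- list()
  haps <- list()
  co_rec <- list()
  for (ch in chroms) {
    m <- map[map$chrom == ch, ]
    ns <- nrow(m)
    f <- stats::rbeta(ns, config$maf_shape1, config$maf_shape2)
    f <- pmin(pmax(f, 0.05), 0.95)
    H <- matrix(NA_integer_, ns, 2L * n)
    colnames(H) <- paste0(rep(iid, each = 2L), "|", c(0L, 1L))
    for (j in seq_len(n)) {
      cols <- c(2L * j - 1L, 2L * j)
      if (is.na(fa_idx[j])) {
        H[, cols] <- stats::rbinom(2L * ns, 1L, f)
      } else {
        for (k in 1:2) {
          pj <- if (k == 1) fa_idx[j] else mo_idx[j]
          mei <- simulate_meiosis(H[, c(2L * pj - 1L, 2L * pj)],
                                  if (k == 1) "male" else "female", m, ch)
          H[, cols[k]] <- mei$gamete
          if (length(mei$crossovers)) {
            co_rec[[length(co_rec) + 1L]] <- tibble::tibble(
              iid = iid[j], parent = iid[if (k == 1) fa_idx[j] else mo_idx[j]],
              parent_sex = if (k == 1) "male" else "female",
              hap = k - 1L, chrom = ch, pos = mei$crossovers)
          }
        }
      }
    }
    freqs[[ch]] <- f
    haps[[ch]] <- H
  }

  x_haps <- NULL
  if (has_x) {
    mx <- map[map$chrom == "X", ]
    ns <- nrow(mx)
    fx <- pmin(pmax(stats::rbeta(ns, config$maf_shape1, config$maf_shape2),
                    0.05), 0.95)
    x_haps <- matrix(NA_integer_, ns, 2L * n)
    colnames(x_haps) <- paste0(rep(iid, each = 2L), "|", c(0L, 1L))
    for (j in seq_len(n)) {
      cols <- c(2L * j - 1L, 2L * j)
      if (is.na(fa_idx[j])) {
        if (ped$sex[j] == 2L) {
          x_haps[, cols] <- stats::rbinom(2L * ns, 1L, fx)
        } else {
          x_haps[, cols[2]] <- stats::rbinom(ns, 1L, fx)
        }
      } else {
        # maternal X: recombinant of mother's two X haplotypes
        mo_cols <- c(2L * mo_idx[j] - 1L, 2L * mo_idx[j])
        mei <- simulate_meiosis(x_haps[, mo_cols], "female", map, "X")
        x_haps[, cols[2]] <- mei$gamete
        if (ped$sex[j] == 2L) {
          # paternal X: father's single X, transmitted without recombination
          x_haps[, cols[1]] <- x_haps[, 2L * fa_idx[j]]
        }
      }
    }
  }

  mt <- NULL
  if (config$mt_sites > 0) {
    fmt <- stats::rbeta(config$mt_sites, 0.5, 3)
    mt <- matrix(NA_integer_, config$mt_sites, n)
    colnames(mt) <- iid
    for (j in seq_len(n)) {
      mt[, j] <- if (is.na(mo_idx[j])) {
        stats::rbinom(config$mt_sites, 1L, fmt)
      } else {
        v <- mt[, mo_idx[j]]
        flip <- stats::runif(config$mt_sites) < config$mt_mutation_rate
        as.integer(xor(v, flip))
      }
    }
    if (config$mt_noise > 0) {
      noise <- matrix(stats::runif(length(mt)) < config$mt_noise, nrow(mt))
      mt <- matrix(as.integer(xor(mt == 1L, noise)), nrow(mt),
                   dimnames = dimnames(mt))
    }
  }

  samples <- tibble::tibble(iid = ped$id, sex = ped$sex, age = ped$age,
                            family = ped$family, family_type = ped$type,
                            role = ped$role, genotyped = ped$genotyped)
  cohort <- structure(
    list(map = map, samples = samples,
         pedigree = tibble::tibble(iid = ped$id, father = ped$father,
                                   mother = ped$mother),
         haps = haps, obs = NULL, x_haps = x_haps, mt = mt, freqs = freqs,
         sides = sides, sib_pairs = sibs,
         crossovers = if (length(co_rec)) dplyr::bind_rows(co_rec) else
           tibble::tibble(iid = character(), parent = character(),
                          parent_sex = character(), hap = integer(),
                          chrom = character(), pos = numeric()),
         config = config),
    class = "pofo_cohort")
  corrupt_cohort(cohort, config$genotype_error, config$switch_error)
}

#' Corrupt truth haplotypes into observed data
#'
#' Applies per-allele genotype flips at `genotype_error`, and phase switch
#' errors as a Poisson process along the sex-averaged cM scale at
#' `switch_error` per cM. Each chromosome's observed haplotype pair also
#' starts in a random orientation, emulating the arbitrary per-chromosome
#' haplotype order of statistical phasing. Truth is retained in `$haps`.
#'
#' @param cohort A `pofo_cohort`.
#' @param genotype_error Per-allele flip probability in `[0, 1)`.
#' @param switch_error Switch rate per centimorgan, `>= 0`.
#' @param random_orientation Start each chromosome in a random haplotype
#'   orientation (default `TRUE`; with rates 0 and `FALSE` the observed data
#'   equal truth).
#' @return The cohort with `$obs` replaced.
#' @export
corrupt_cohort <- function(cohort, genotype_error, switch_error,
                           random_orientation = TRUE) {
  stopifnot(inherits(cohort, "pofo_cohort"),
            genotype_error >= 0, genotype_error < 1, switch_error >= 0)
  n <- nrow(cohort$samples)
  obs <- purrr::imap(cohort$haps, function(H, ch) {
    m <- cohort$map[cohort$map$chrom == ch, ]
    cm <- (m$cm_female + m$cm_male) / 2
    L <- max(cm) - min(cm)
    O <- H
    for (j in seq_len(n)) {
      cols <- c(2L * j - 1L, 2L * j)
      init <- if (random_orientation) sample(0:1, 1L) else 0L
      n_sw <- if (switch_error > 0) stats::rpois(1L, switch_error * L) else 0L
      o <- rep.int(init, nrow(m))
      if (n_sw > 0) {
        sw <- sort(stats::runif(n_sw, min(cm), max(cm)))
        o <- (init + findInterval(cm, sw)) %% 2L
      }
      swap <- o == 1L
      if (any(swap)) {
        tmp <- O[swap, cols[1]]
        O[swap, cols[1]] <- O[swap, cols[2]]
        O[swap, cols[2]] <- tmp
      }
    }
    if (genotype_error > 0) {
      flip <- matrix(stats::runif(length(O)) < genotype_error, nrow(O))
      O <- matrix(as.integer(xor(O == 1L, flip)), nrow(O),
                  dimnames = dimnames(O))
    }
    O
  })
  cohort$obs <- obs
  cohort
}

#' @export
print.pofo_cohort <- function(x, ...) {
  cat("<pofo_cohort> ", sum(x$samples$genotyped), " genotyped of ",
      nrow(x$samples), " individuals, ",
      length(x$haps), " autosome(s), ",
      sum(vapply(x$haps, nrow, 1L)), " sites",
      if (!is.null(x$x_haps)) paste0(", X (", nrow(x$x_haps), " sites)"),
      if (!is.null(x$mt)) paste0(", mtDNA (", nrow(x$mt), " sites)"),
      "\n", sep = "")
  invisible(x)
}

#' Extract genotype dosages from a cohort
#'
#' @param cohort A `pofo_cohort`.
#' @param chroms Chromosomes to stack (default: all autosomes).
#' @param use `"observed"` or `"truth"` haplotypes.
#' @param genotyped_only Restrict columns to genotyped individuals.
#' @return Integer matrix, sites x individuals, entries 0/1/2.
#' @export
cohort_genotypes <- function(cohort, chroms = NULL,
                             use = c("observed", "truth"),
                             genotyped_only = TRUE) {
  use <- match.arg(use)
  src <- if (use == "observed") cohort$obs else cohort$haps
  chroms <- chroms %||% names(src)
  ids <- cohort$samples$iid
  if (genotyped_only) ids <- ids[cohort$samples$genotyped]
  G <- do.call(rbind, purrr::map(src[chroms], function(H) {
    H[, paste0(rep(ids, each = 2), "|", c(0L, 1L)), drop = FALSE]
  }))
  out <- G[, seq(1, ncol(G), by = 2), drop = FALSE] +
    G[, seq(2, ncol(G), by = 2), drop = FALSE]
  colnames(out) <- ids
  out
}

#' Haplotype pair of one individual
#'
#' @param cohort A `pofo_cohort`.
#' @param iid Individual id.
#' @param chrom Chromosome.
#' @param use `"observed"` or `"truth"`.
#' @return Integer matrix `n_sites x 2` (columns hap 0, hap 1; on truth data
#'   hap 0 is paternal).
#' @export
cohort_haps <- function(cohort, iid, chrom, use = c("observed", "truth")) {
  use <- match.arg(use)
  src <- if (use == "observed") cohort$obs else cohort$haps
  H <- src[[chrom]][, paste0(iid, "|", 0:1), drop = FALSE]
  colnames(H) <- c("0", "1")
  H
}

#' Simulate phenotypes under parent-of-origin effects
#'
#' Builds a quantitative or binary trait from parental alleles at causal
#' variants: `y = sum(beta_pat * a_pat + beta_mat * a_mat) + covariate effects
#' + noise` (logistic link for binary traits). Setting `beta_pat = b` and
#' `beta_mat = -b` produces a bipolar effect whose additive component cancels
#' in heterozygotes.
#'
#' @param cohort A `pofo_cohort`.
#' @param effects Tibble with columns `chrom`, `site` (1-based marker index on
#'   that chromosome), `beta_pat`, `beta_mat`.
#' @param noise_sd Residual standard deviation (quantitative) or logistic
#'   scale noise omitted (binary).
#' @param beta_age,beta_sex Covariate effects.
#' @param kind `"quantitative"` or `"binary"`.
#' @param intercept Intercept (log-odds scale for binary).
#' @return Tibble `iid`, `y` for genotyped individuals; the realised causal
#'   effects are attached as attribute `"effects"`.
#' @export
simulate_phenotypes <- function(cohort, effects, noise_sd = 1,
                                beta_age = 0, beta_sex = 0,
                                kind = c("quantitative", "binary"),
                                intercept = 0) {
  kind <- match.arg(kind)
  stopifnot(all(c("chrom", "site", "beta_pat", "beta_mat") %in% names(effects)))
  ids <- cohort$samples$iid[cohort$samples$genotyped]
  score <- stats::setNames(rep(0, length(ids)), ids)
  for (i in seq_len(nrow(effects))) {
    ch <- as.character(effects$chrom[i])
    H <- cohort$haps[[ch]]
    if (is.null(H) || effects$site[i] > nrow(H) || effects$site[i] < 1) {
      stop("unknown causal variant: chrom ", ch, " site ", effects$site[i],
           call. = FALSE)
    }
    a_pat <- H[effects$site[i], paste0(ids, "|0")]
    a_mat <- H[effects$site[i], paste0(ids, "|1")]
    score <- score + effects$beta_pat[i] * a_pat + effects$beta_mat[i] * a_mat
  }
  meta <- cohort$samples[match(ids, cohort$samples$iid), ]
  lin <- intercept + score + beta_age * meta$age + beta_sex * (meta$sex - 1)
  y <- if (kind == "quantitative") {
    lin + stats::rnorm(length(ids), 0, noise_sd)
  } else {
    stats::rbinom(length(ids), 1L, stats::plogis(lin))
  }
  out <- tibble::tibble(iid = ids, y = y)
  attr(out, "effects") <- effects
  out
}

#' Simulate a ready-encoded POE association dataset
#'
#' A lightweight generator for association-scan validation that skips pedigree
#' simulation: unrelated individuals receive independent parental alleles at
#' each variant, a trait built from per-variant paternal/maternal effects, and
#' imputation-like haploid dosages (`ap_mat`, `ap_pat`) equal to the truth
#' alleles perturbed by optional noise. Per-variant INFO scores and allele
#' frequencies are emitted so downstream variant filters are exercisable.
#'
#' @param n Individuals.
#' @param n_variants Variants.
#' @param beta_pat,beta_mat Per-variant effect sizes (recycled).
#' @param maf Per-variant allele frequencies (recycled; default drawn
#'   uniformly in `[0.05, 0.5]`).
#' @param p_t Per-individual parental assignment probability in `[0.5, 1]`
#'   (recycled).
#' @param ap_noise SD of truncated Gaussian noise added to haploid dosages.
#' @param noise_sd Residual trait SD.
#' @param kind `"quantitative"` or `"binary"`.
#' @param seed Optional seed.
#' @return A list with matrices `ap_mat`, `ap_pat` (`n x n_variants`), tibble
#'   `variants` (`variant_id`, `chrom`, `pos`, `maf`, `info`, truth betas),
#'   tibble `phenotype` (`iid`, `y`), and `p_t`.
#' @export
sim_poe_dataset <- function(n, n_variants, beta_pat = 0, beta_mat = 0,
                            maf = NULL, p_t = 1, ap_noise = 0, noise_sd = 1,
                            kind = c("quantitative", "binary"), seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  maf <- if (is.null(maf)) stats::runif(n_variants, 0.05, 0.5) else
    rep_len(maf, n_variants)
  beta_pat <- rep_len(beta_pat, n_variants)
  beta_mat <- rep_len(beta_mat, n_variants)
  p_t <- rep_len(p_t, n)
  a_pat <- vapply(maf, function(f) stats::rbinom(n, 1L, f),
                  integer(n))
  a_mat <- vapply(maf, function(f) stats::rbinom(n, 1L, f),
                  integer(n))
  lin <- a_pat %*% beta_pat + a_mat %*% beta_mat
  y <- if (kind == "quantitative") {
    as.numeric(lin) + stats::rnorm(n, 0, noise_sd)
  } else {
    stats::rbinom(n, 1L, stats::plogis(as.numeric(lin)))
  }
  jitter_ap <- function(a) {
    if (ap_noise <= 0) return(a * 1.0)
    pmin(pmax(a + stats::rnorm(length(a), 0, ap_noise), 0), 1)
  }
  iid <- sprintf("I%05d", seq_len(n))
  vid <- sprintf("v%05d", seq_len(n_variants))
  ap_mat <- jitter_ap(a_mat); dimnames(ap_mat) <- list(iid, vid)
  ap_pat <- jitter_ap(a_pat); dimnames(ap_pat) <- list(iid, vid)
  list(
    ap_mat = ap_mat, ap_pat = ap_pat,
    variants = tibble::tibble(
      variant_id = vid, chrom = "1",
      pos = seq_len(n_variants) * 1e4, maf = maf,
      info = stats::rbeta(n_variants, 20, 1),
      beta_pat = beta_pat, beta_mat = beta_mat),
    phenotype = tibble::tibble(iid = iid, y = y),
    p_t = stats::setNames(p_t, iid)
  )
}

#' Simulate independent sibling pairs
#'
#' Generates `n_pairs` sibling pairs (two founder parents each, never
#' genotyped) with truth-phased haplotypes over the given map: haplotype 0
#' paternal, haplotype 1 maternal. Used to validate crossover inference and
#' the sex-specific crossover score against truth at scale without full
#' cohort bookkeeping.
#'
#' @param n_pairs Number of sibling pairs.
#' @param map Genetic map tibble (autosomes only are used).
#' @param maf_shape1,maf_shape2 Founder allele-frequency Beta parameters
#'   (truncated to `[0.05, 0.95]`).
#' @return A list of length `n_pairs`; each element has `target` and `sib`
#'   (named lists, chromosome -> `n_sites x 2` integer matrix) and `meioses`,
#'   a tibble recording every meiosis' truth crossover positions and
#'   starting parental haplotype (`sibling`, `hap`, `chrom`, `start_hap`,
#'   `crossovers` as a list column).
#' @export
sim_sibling_pairs <- function(n_pairs, map, maf_shape1 = 0.8,
                              maf_shape2 = 0.8) {
  chroms <- setdiff(unique(map$chrom), "X")
  grids <- purrr::map(chroms, ~map[map$chrom == .x, ])
  names(grids) <- chroms
  freqs <- purrr::map(grids, function(m) {
    pmin(pmax(stats::rbeta(nrow(m), maf_shape1, maf_shape2), 0.05), 0.95)
  })
  purrr::map(seq_len(n_pairs), function(i) {
    t_h <- s_h <- list()
    mei <- list()
    for (ch in chroms) {
      f <- freqs[[ch]]
      ns <- length(f)
      fa <- matrix(stats::rbinom(2L * ns, 1L, f), ns)
      mo <- matrix(stats::rbinom(2L * ns, 1L, f), ns)
      for (who in c("target", "sib")) {
        mp <- simulate_meiosis(fa, "male", map, ch)
        mm <- simulate_meiosis(mo, "female", map, ch)
        h <- cbind(`0` = mp$gamete, `1` = mm$gamete)
        if (who == "target") t_h[[ch]] <- h else s_h[[ch]] <- h
        mei[[length(mei) + 1L]] <- tibble::tibble(
          sibling = who, hap = c(0L, 1L), chrom = ch,
          start_hap = c(mp$start, mm$start),
          crossovers = list(mp$crossovers, mm$crossovers))
      }
    }
    list(target = t_h, sib = s_h, meioses = dplyr::bind_rows(mei))
  })
}

#' Truth IBD breakends of a simulated sibling pair
#'
#' Error-free crossover calls derived from the simulator's ground truth: on
#' each parental track (haplotype 0 paternal, 1 maternal) the two siblings'
#' gametes share a grandparental haplotype exactly between crossovers of the
#' two meioses, so the truth IBD segment boundaries are the recorded
#' crossover positions themselves. Shared segments shorter than `min_cm`
#' (sex-averaged) are censored as in detection, and chromosome ends are not
#' breakends.
#'
#' @param pair One element of [sim_sibling_pairs()] output (uses `$meioses`).
#' @param map Genetic map tibble.
#' @param min_cm Shared-segment length floor in cM (default 3; `0` disables
#'   censoring).
#' @return Tibble `chrom`, `pos`, `hap` of breakend crossover calls.
#' @export
truth_sib_breakends <- function(pair, map, min_cm = 3) {
  mei <- pair$meioses
  out <- list()
  for (ch in unique(mei$chrom)) {
    m <- map[map$chrom == ch, ]
    for (h in c(0L, 1L)) {
      rows <- mei[mei$chrom == ch & mei$hap == h, ]
      b <- sort(unique(c(rows$crossovers[[1]], rows$crossovers[[2]])))
      shared0 <- rows$start_hap[1] == rows$start_hap[2]
      edges <- c(min(m$pos), b, max(m$pos))
      shared <- shared0 == (seq_len(length(edges) - 1L) %% 2L == 1L)
      cm <- interpolate_cm(map, ch, edges)$cm_avg
      keep_seg <- shared & (cm[-1] - cm[-length(cm)]) >= min_cm
      ends <- unique(c(edges[-length(edges)][keep_seg],
                       edges[-1][keep_seg]))
      ends <- ends[ends %in% b]
      if (length(ends)) {
        out[[length(out) + 1L]] <- tibble::tibble(chrom = ch, pos = ends,
                                                  hap = h)
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(chrom = character(), pos = numeric(),
                          hap = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$hap, .data$pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
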