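test_that("meiosis on a zero-length map transmits one whole haplotype", {
  map <- tibble::tibble(chrom = "1", pos = seq(1, 1000, length.out = 50),
                        cm_female = rep(0, 50), cm_male = rep(0, 50))
  haps <- cbind(rep(0L, 50), rep(1L, 50))
  set.seed(1)
  out <- simulate_meiosis(haps, "female", map, "1")
  expect_length(out$crossovers, 0)
  expect_true(all(out$gamete == 0L) || all(out$gamete == 1L))
  expect_error(simulate_meiosis(haps, "male", map, "2"), "empty map")
})

test_that("crossover counts are Poisson with the sex-specific map length", {
  set.seed(3)
  map <- sim_genetic_map(n_chrom = 1, n_sites = 300, cm_female = 250,
                         cm_male = 200)
  haps <- cbind(rep(0L, 300), rep(1L, 300))
  n <- vapply(1:4000, function(i) {
    length(simulate_meiosis(haps, "male", map, "1")$crossovers)
  }, 0L)
  expect_equal(mean(n), 2.0, tolerance = 0.05)
  expect_equal(var(n), 2.0, tolerance = 0.15)
  nf <- vapply(1:2000, function(i) {
    length(simulate_meiosis(haps, "female", map, "1")$crossovers)
  }, 0L)
  expect_equal(mean(nf), 2.5, tolerance = 0.1)
})

test_that("a single crossover splits the gamete at its position", {
  # construct a meiosis whose only crossover must land in one interval:
  # all recombination concentrated between sites 25 and 26
  cmf <- c(rep(0, 25), rep(100, 25))
  map <- tibble::tibble(chrom = "1", pos = seq(10, 1000, length.out = 50),
                        cm_female = cmf, cm_male = cmf)
  haps <- cbind(rep(0L, 50), rep(1L, 50))
  set.seed(4)
  reps <- replicate(50, simulate_meiosis(haps, "male", map, "1"),
                    simplify = FALSE)
  one <- Filter(function(r) length(r$crossovers) == 1, reps)
  expect_gt(length(one), 0)
  for (r in one) {
    k <- findInterval(map$pos, r$crossovers)
    expect_true(all(r$gamete == r$gamete[1] | k == 1))
    expect_true(all(r$gamete[k == 1] != r$gamete[1]))
  }
})

test_that("cohorts are reproducible bit-for-bit under a fixed seed", {
  cfg <- sim_config(n_families = 5, seed = 77,
                    map_args = list(n_chrom = 2, n_sites = 150,
                                    include_x = TRUE))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$haps, b$haps)
  expect_identical(a$obs, b$obs)
  expect_identical(a$mt, b$mt)
  expect_identical(a$samples, b$samples)
})

test_that("trio and avuncular truth kinship match pedigree expectations", {
  ch <- fix_cohort()
  G <- cohort_genotypes(ch, use = "truth", genotyped_only = FALSE)
  smp <- ch$samples
  d1 <- ch$sides[ch$sides$degree == 1, ]
  k1 <- kinship_ibs(G, tibble::tibble(id_a = d1$target, id_b = d1$relative),
                    min_sites = 500)
  expect_equal(mean(k1$kinship), 0.25, tolerance = 0.02)
  d2 <- ch$sides[ch$sides$degree == 2, ]
  k2 <- kinship_ibs(G, tibble::tibble(id_a = d2$target, id_b = d2$relative),
                    min_sites = 500)
  # realized kinship of 2nd-degree pairs varies noticeably on a ~19-Morgan
  # simulated genome; the mean over ~20 pairs carries that pedigree variance
  expect_equal(mean(k2$kinship), 0.125, tolerance = 0.15)
  # founders from different families are unrelated
  f <- smp$iid[smp$role == "father"][1:10]
  cmb <- t(utils::combn(f, 2))
  k0 <- kinship_ibs(G, tibble::tibble(id_a = cmb[, 1], id_b = cmb[, 2]),
                    min_sites = 500)
  expect_lt(max(abs(k0$kinship)), 0.03)
  expect_error(simulate_cohort(sim_config(n_families = 0)), "n_families")
})

test_that("corruption rates reproduce their nominal counts", {
  cfg <- sim_config(n_families = 6, seed = 5, genotype_error = 0,
                    switch_error = 0,
                    map_args = list(n_chrom = 2, n_sites = 400,
                                    include_x = TRUE))
  ch <- simulate_cohort(cfg)
  clean <- corrupt_cohort(ch, 0, 0, random_orientation = FALSE)
  expect_identical(clean$obs, clean$haps)
  # genotype flips ~ binomial count
  err <- corrupt_cohort(ch, 0.01, 0, random_orientation = FALSE)
  n_alleles <- sum(vapply(ch$haps, length, 1L))
  flips <- sum(vapply(names(ch$haps), function(c_) {
    sum(err$obs[[c_]] != ch$haps[[c_]])
  }, 0))
  expect_equal(flips / n_alleles, 0.01, tolerance = 0.15)
  # switch count ~ rate x genetic length (per cM)
  lens <- map_lengths(ch$map)
  L <- sum(lens$l_c[lens$chrom != "X"]) * 100
  set.seed(8)
  counts <- replicate(300, {
    sw <- corrupt_cohort(ch, 0, 0.02, random_orientation = FALSE)
    iid <- ch$samples$iid[1]
    sum(vapply(names(ch$haps), function(c_) {
      o <- sw$obs[[c_]][, paste0(iid, "|0")] != ch$haps[[c_]][, paste0(iid, "|0")]
      het <- ch$haps[[c_]][, paste0(iid, "|0")] != ch$haps[[c_]][, paste0(iid, "|1")]
      oh <- o[het]
      if (length(oh) > 1) sum(diff(oh) != 0) + oh[1] else 0L
    }, 0L))
  })
  expect_equal(mean(counts), 0.02 * L, tolerance = 0.2)
})

test_that("mtDNA follows the maternal line only", {
  ch <- fix_cohort()
  ped <- ch$pedigree
  kids <- ped[!is.na(ped$mother), ]
  dm <- vapply(seq_len(nrow(kids)), function(i) {
    mean(ch$mt[, kids$iid[i]] != ch$mt[, kids$mother[i]])
  }, 0)
  # mother-child mtDNA differs only at mutation + call-noise sites
  expect_lt(mean(dm), 0.02)
  # unrelated founders share only population-level minors
  f <- ped$iid[is.na(ped$mother)][1:20]
  cmb <- t(utils::combn(f, 2))
  dv <- vapply(seq_len(nrow(cmb)), function(i) {
    mvs(ch$mt[, cmb[i, 1]], ch$mt[, cmb[i, 2]])
  }, 0)
  self <- vapply(f, function(id) mvs(ch$mt[, id], ch$mt[, id]), 0)
  expect_lt(mean(dv), mean(self) / 2)
})

test_that("phenotype simulation realises the requested parental effects", {
  ch <- fix_cohort()
  eff0 <- tibble::tibble(chrom = "1", site = 10L, beta_pat = 0, beta_mat = 0)
  set.seed(11)
  y0 <- simulate_phenotypes(ch, eff0)
  g <- cohort_genotypes(ch, chroms = "1", use = "truth")[10, y0$iid]
  expect_gt(cor.test(y0$y, g)$p.value, 0.01)
  expect_error(
    simulate_phenotypes(ch, tibble::tibble(chrom = "99", site = 1,
                                           beta_pat = 1, beta_mat = 0)),
    "unknown causal variant")
  # bipolar: no additive signal, strong heterozygote parental contrast
  effb <- tibble::tibble(chrom = "1", site = 20L, beta_pat = 1, beta_mat = -1)
  yb <- simulate_phenotypes(ch, effb, noise_sd = 0.5)
  a_pat <- ch$haps[["1"]][20, paste0(yb$iid, "|0")]
  a_mat <- ch$haps[["1"]][20, paste0(yb$iid, "|1")]
  het <- a_pat + a_mat == 1
  # the additive slope is null up to sampling noise (~80 individuals),
  # far below the per-parent effect of 1
  expect_lt(abs(coef(lm(yb$y ~ I(a_pat + a_mat)))[2]), 0.5)
  contrast <- mean(yb$y[het & a_pat == 1]) - mean(yb$y[het & a_mat == 1])
  expect_equal(contrast, 2, tolerance = 0.3)
})
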