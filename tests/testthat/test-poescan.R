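test_that("phenotype preparation averages time points then rank-transforms", {
  # symmetric output, median at zero
  r <- tibble::tibble(iid = letters[1:5], value = 1:5)
  y <- prep_phenotype(r)
  expect_equal(sort(y$y), -sort(y$y, decreasing = TRUE))
  expect_equal(y$y[y$iid == "c"], 0)
  # two time points averaged before the transform
  r2 <- tibble::tibble(iid = c("a", "a", "b"), value = c(10, 14, 20))
  y2 <- prep_phenotype(r2)
  expect_equal(nrow(y2), 2)
  # matches an independent rank-then-quantile evaluation
  set.seed(81)
  v <- rnorm(200)
  expect_equal(int_transform(v),
               qnorm((rank(v) - 0.5) / 200))
  # binary definition by inclusion/exclusion code lists
  rec <- tibble::tibble(iid = c("a", "b", "b", "c"),
                        code = c("E11", "E11", "E10", "E10"))
  yb <- prep_phenotype(rec, kind = "binary", include_codes = "E11",
                       exclude_codes = "E10", ids = letters[1:5])
  expect_equal(yb$y[yb$iid == "a"], 1L)
  expect_false("b" %in% yb$iid) # carries an exclusion code
  expect_false("c" %in% yb$iid)
  expect_equal(yb$y[yb$iid == "d"], 0L)
})

test_that("the differential Z statistic matches its normal-CDF oracle", {
  z0 <- differential_z(0.3, 0.1, 0.3, 0.2)
  expect_equal(z0$z_d, 0)
  expect_equal(z0$p_d, 1)
  # published total-protein summary statistics
  z1 <- differential_z(0.101, 0.032, -0.106, 0.032)
  expect_equal(z1$z_d, 4.574, tolerance = 1e-3)
  expect_equal(z1$p_d, 4.8e-6, tolerance = 0.01)
  # doubling both standard errors halves the statistic
  z2 <- differential_z(0.101, 0.064, -0.106, 0.064)
  expect_equal(z2$z_d, z1$z_d / 2)
  expect_error(differential_z(1, 0, 1, 1))
})

test_that("POE classification reproduces the five-way rules", {
  expect_equal(as.character(classify_poe(-0.055 / 0.011, 0.034 / 0.010)),
               "bipolar")
  expect_equal(as.character(classify_poe(-6.75, 1.25)), "paternal")
  expect_equal(as.character(classify_poe(-15.25, -8.5)),
               "paternal_asymmetric")
  expect_equal(as.character(classify_poe(0.5, 4)), "maternal")
  expect_equal(as.character(classify_poe(3, 5)), "maternal_asymmetric")
  expect_true(is.na(classify_poe(0, 3)))
  expect_true(is.na(classify_poe(Inf, 3)))
  # parent-swap maps each class to its mirror
  set.seed(82)
  zp <- rnorm(200, 0, 3); zm <- rnorm(200, 0, 3)
  a <- classify_poe(zp, zm)
  b <- classify_poe(zm, zp)
  mirror <- c(bipolar = "bipolar", maternal = "paternal",
              maternal_asymmetric = "paternal_asymmetric",
              paternal = "maternal", paternal_asymmetric =
                "maternal_asymmetric")
  ok <- !is.na(a)
  expect_equal(unname(mirror[as.character(a[ok])]), as.character(b[ok]))
  # the five classes partition the generic plane
  expect_true(all(!is.na(a[zp != 0 & zm != 0])))
})

test_that("effective test counts follow the eigenvalue rule", {
  expect_equal(n_eff(diag(7)), 7L)
  expect_equal(n_eff(matrix(1, 2, 2)), 1L)
  # three independent blocks of perfectly correlated traits
  B <- matrix(0, 6, 6)
  B[1:2, 1:2] <- 1; B[3:4, 3:4] <- 1; B[5:6, 5:6] <- 1
  expect_equal(n_eff(B), 3L)
  expect_error(n_eff(matrix(c(1, 2, 2, 1), 2)), "positive semi-definite")
})

test_that("significance thresholds reproduce the published arithmetic", {
  th <- poe_thresholds(48, n_additive = 1812, n_imprinted_tests = 16574)
  v <- stats::setNames(th$value, th$threshold)
  expect_equal(unname(v["genome_wide"]), 5e-8 / 48)
  expect_equal(unname(v["genome_wide"]), 1e-9, tolerance = 0.05)
  expect_equal(unname(v["additive_region"]), 2.75e-5, tolerance = 0.01)
  expect_equal(unname(v["imprinted_suggestive"]), 3.01e-6, tolerance = 0.01)
  expect_equal(unname(v["imprinted_significant"]), 6.27e-8, tolerance = 0.01)
})

test_that("pruning keeps the strongest independent hits", {
  res <- tibble::tibble(variant_id = c("a", "b", "c"),
                        chrom = c("1", "1", "1"),
                        pos = c(1e6, 1.1e6, 5e6),
                        p = c(1e-10, 1e-8, 1e-9))
  kept <- prune_hits(res)
  expect_setequal(kept$variant_id, c("a", "c")) # b within 500 kb of a
  # LD pruning via r-squared
  set.seed(83)
  g1 <- rbinom(400, 2, 0.3)
  G <- cbind(a = g1, b = rbinom(400, 2, 0.3),
             c = ifelse(runif(400) < 0.95, g1, rbinom(400, 2, 0.3)))
  res2 <- tibble::tibble(variant_id = c("a", "b", "c"),
                         chrom = "1", pos = c(1e6, 2e6, 3e6),
                         p = c(1e-10, 1e-8, 1e-9))
  kept2 <- prune_hits(res2, genotypes = G)
  expect_setequal(kept2$variant_id, c("a", "b")) # c is an LD proxy of a
})

test_that("association scans recover simulated parental effects", {
  d <- sim_poe_dataset(5000, 8, beta_pat = 0.3, beta_mat = 0.1, maf = 0.3,
                       seed = 84)
  enc <- pofo_encoding(d$ap_mat, d$ap_pat, variants = d$variants)
  sp <- assoc_scan(enc, d$phenotype, mode = "pat")
  sm <- assoc_scan(enc, d$phenotype, mode = "mat")
  expect_true(all(abs(sp$beta - 0.3) < 3 * sp$se))
  expect_true(all(abs(sm$beta - 0.1) < 3 * sm$se))
  expect_equal(mean(sp$beta), 0.3, tolerance = 0.1)
  expect_equal(mean(sm$beta), 0.1, tolerance = 0.3)
  sd_ <- assoc_scan(enc, d$phenotype, mode = "diff")
  expect_true(all(sd_$p < 1e-2))
  expect_lt(median(sd_$p), 1e-3)
  # P consistent with beta/se under the reported test
  expect_equal(sd_$p, 2 * pt(abs(sd_$beta / sd_$se), sd_$n - 2,
                             lower.tail = FALSE), tolerance = 1e-8)
  # broom-style accessors
  td <- tidy(sp)
  expect_equal(td$estimate, sp$beta)
  expect_gt(glance(sp)$lambda_gc, 1) # true signal inflates the median
  # binary trait path
  db <- sim_poe_dataset(3000, 4, beta_pat = 0.4, beta_mat = 0.4,
                        kind = "binary", seed = 85)
  eb <- pofo_encoding(db$ap_mat, db$ap_pat, variants = db$variants)
  sb <- assoc_scan(eb, db$phenotype, mode = "add", kind = "binary")
  expect_true(all(abs(sb$beta - 0.4) < 3 * sb$se))
})

test_that("conditional scans remove LD proxies but keep independent signals", {
  set.seed(86)
  n <- 3000
  a_pat <- rbinom(n, 1, 0.3); a_mat <- rbinom(n, 1, 0.3)
  b_pat <- rbinom(n, 1, 0.4); b_mat <- rbinom(n, 1, 0.4)
  # proxy: near-copy of the causal variant
  keep <- runif(n) < 0.97
  p_pat <- ifelse(keep, a_pat, rbinom(n, 1, 0.3))
  p_mat <- ifelse(keep, a_mat, rbinom(n, 1, 0.3))
  ap_mat <- cbind(lead = a_mat, indep = b_mat, proxy = p_mat) * 1.0
  ap_pat <- cbind(lead = a_pat, indep = b_pat, proxy = p_pat) * 1.0
  iid <- sprintf("i%04d", 1:n)
  dimnames(ap_mat) <- dimnames(ap_pat) <- list(iid, c("lead", "indep",
                                                      "proxy"))
  y <- 0.5 * a_pat - 0.5 * a_mat + 0.5 * b_pat - 0.5 * b_mat + rnorm(n)
  enc <- pofo_encoding(ap_mat, ap_pat)
  pheno <- tibble::tibble(iid = iid, y = y)
  cs <- conditional_scan(enc, pheno, lead_variant = "lead")
  expect_true(cs$collinear[cs$variant_id == "lead"])
  expect_true(is.na(cs$p[cs$variant_id == "lead"]))
  expect_lt(cs$p[cs$variant_id == "indep"], 1e-4)
  expect_gt(cs$p[cs$variant_id == "proxy"], 1e-3)
})

test_that("sex-difference and heritability contrasts behave", {
  s0 <- sex_diff_z(0.2, 0.05, 0.2, 0.05)
  expect_equal(s0$z, 0)
  expect_equal(s0$p, 1)
  expect_equal(sex_diff_z(0.3, 0.1, 0.1, 0.1)$z,
               -sex_diff_z(0.1, 0.1, 0.3, 0.1)$z)
  h <- h2_diff_z(0.2, 0.05, 0.1, 0.05)
  expect_equal(h$z, sqrt(2), tolerance = 1e-12)
  expect_equal(h2_diff_z(0.2, 0.1, 0.2, 0.1)$z, 0)
})

test_that("odds-ratio contrasts recover the published worked example", {
  r <- or_ratio(1.14, c(1.08, 1.21), 0.91, c(0.86, 0.96))
  expect_equal(r$ratio, 1.25, tolerance = 0.005)
  expect_equal(r$lower, 1.16, tolerance = 0.005)
  # equal parental odds: ratio one; swapping parents inverts it
  expect_equal(or_ratio(1.2, c(1.1, 1.3), 1.2, c(1.1, 1.3))$ratio, 1)
  inv <- or_ratio(0.91, c(0.86, 0.96), 1.14, c(1.08, 1.21))
  expect_equal(inv$ratio, 1 / r$ratio)
  expect_error(or_ratio(1.2, c(1.3, 1.1), 1, c(0.9, 1.1)), "inverted")
})
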