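test_that("pedigree phasing follows transmission logic", {
  out <- pedigree_phase(child = c(1L, 1L, 0L, 2L, 1L),
                        father = c(2L, 1L, 0L, 2L, 0L),
                        mother = c(0L, 1L, 0L, 2L, 2L))
  # child het, father hom AA, mother hom aa: paternal A, maternal a
  expect_equal(out$hap_pat[1], 1L)
  expect_equal(out$hap_mat[1], 0L)
  # triple heterozygote: unresolved by logic alone
  expect_false(out$resolved[2])
  # homozygous child: trivially resolved
  expect_equal(out$hap_pat[3], 0L)
  expect_equal(out$hap_mat[4], 1L)
  # child het, father hom 0, mother hom 2
  expect_equal(out$hap_pat[5], 0L)
  expect_equal(out$hap_mat[5], 1L)
  # Mendel-inconsistent site is masked
  bad <- pedigree_phase(child = 2L, father = 0L, mother = 2L)
  expect_true(bad$mendel_masked)
  expect_true(is.na(bad$hap_pat))
  # one parent: the other side follows by exclusion
  one <- pedigree_phase(child = 1L, father = 2L)
  expect_equal(one$hap_pat, 1L)
  expect_equal(one$hap_mat, 0L)
  expect_error(pedigree_phase(child = 1L), "at least one parent")
})

test_that("simulated trios phase resolvable heterozygotes correctly", {
  ch <- fix_cohort()
  smp <- ch$samples
  fams <- unique(smp$family[smp$family_type == "trio"])
  n_ok <- n_tot <- 0
  for (fm in fams) {
    tg <- paste0(fm, "_t")
    for (c_ in names(ch$haps)) {
      gt <- function(id) {
        h <- cohort_haps(ch, id, c_, "truth"); h[, 1] + h[, 2]
      }
      ph <- pedigree_phase(gt(tg), gt(paste0(fm, "_fa")),
                           gt(paste0(fm, "_mo")))
      truth <- cohort_haps(ch, tg, c_, "truth")
      het <- truth[, 1] != truth[, 2]
      sel <- het & ph$resolved
      n_ok <- n_ok + sum(ph$hap_pat[sel] == truth[sel, 1])
      n_tot <- n_tot + sum(sel)
    }
  }
  expect_gt(n_tot, 1000)
  expect_gte(n_ok / n_tot, 0.999)
})

test_that("scaffold anchors are forced onto side-consistent haplotypes", {
  # two chromosomes with single anchors on opposite observed indices
  map <- tibble::tibble(chrom = rep(c("1", "2"), each = 100),
                        pos = rep(seq_len(100) * 1e4, 2),
                        cm_female = rep((seq_len(100) - 1) * 0.5, 2),
                        cm_male = rep((seq_len(100) - 1) * 0.5, 2))
  set.seed(41)
  h1 <- cbind(`0` = rbinom(100, 1, .5), `1` = rbinom(100, 1, .5))
  h2 <- cbind(`0` = rbinom(100, 1, .5), `1` = rbinom(100, 1, .5))
  segs <- tibble::tibble(chrom = c("1", "2"), start_idx = c(10L, 10L),
                         end_idx = c(60L, 60L), hap = c(0L, 1L),
                         group = "G1", n_sites = 51L)
  out <- scaffold_phase(list(`1` = h1, `2` = h2), segs, map)
  expect_equal(out$haps[["1"]], h1)              # already on index 0
  expect_equal(out$haps[["2"]][, 1], h2[, 2])    # re-oriented
  expect_true(all(out$report$anchored))
  # alternating G1/G2 anchors on one observed haplotype force a flip
  segs2 <- tibble::tibble(chrom = "1", start_idx = c(5L, 70L),
                          end_idx = c(30L, 95L), hap = 0L,
                          group = c("G1", "G2"), n_sites = 26L)
  out2 <- scaffold_phase(list(`1` = h1), segs2, map)
  expect_equal(out2$report$n_flips, 1L)
  expect_equal(out2$haps[["1"]][5:30, 1], h1[5:30, 1])
  expect_equal(out2$haps[["1"]][70:95, 2], h1[70:95, 1])
  # unanchored chromosome is untouched and flagged
  out3 <- scaffold_phase(list(`1` = h1, `2` = h2), segs2, map)
  expect_false(out3$report$anchored[out3$report$chrom == "2"])
  expect_equal(out3$haps[["2"]], h2)
})

test_that("dense anchors correct switch errors and the result is idempotent", {
  set.seed(42)
  ns <- 2000
  map <- tibble::tibble(chrom = "1", pos = seq_len(ns) * 1e4,
                        cm_female = (seq_len(ns) - 1) * 0.1,
                        cm_male = (seq_len(ns) - 1) * 0.1)
  truth <- cbind(`0` = rbinom(ns, 1, .5), `1` = rbinom(ns, 1, .5))
  # inject ~10 switch errors
  obs <- truth
  sw <- sort(sample(ns, 10))
  o <- findInterval(seq_len(ns), sw) %% 2 == 1
  obs[o, ] <- obs[o, 2:1]
  # dense anchors: one per interval between switch points, so each anchor
  # is internally phase-consistent (as segments split at mismatches would
  # be) and flips are forced adjacent to the true switch positions
  bounds <- c(1L, sw, ns + 1L)
  blocks <- tibble::tibble(from = bounds[-length(bounds)],
                           to = bounds[-1] - 1L)
  blocks <- blocks[blocks$to - blocks$from + 1L >= 10L, ]
  segs <- tibble::tibble(
    chrom = "1", start_idx = blocks$from, end_idx = blocks$to,
    hap = vapply(seq_len(nrow(blocks)), function(i) {
      idx <- blocks$from[i]:blocks$to[i]
      idx <- idx[truth[idx, 1] != truth[idx, 2]]
      as.integer(mean(obs[idx, 1] != truth[idx, 1]) > 0.5)
    }, 1L),
    group = "G1", n_sites = blocks$to - blocks$from + 1L)
  out <- scaffold_phase(list(`1` = obs), segs, map)
  m_before <- phasing_metrics(list(`1` = obs), list(`1` = truth))
  m_after <- phasing_metrics(out$haps, list(`1` = truth))
  expect_gt(m_before$switch_error_rate, 0.003)
  expect_lt(m_after$switch_error_rate, 0.005)
  expect_lt(m_after$switch_error_rate, m_before$switch_error_rate)
  # every anchor now sits on the side-consistent haplotype index
  for (i in seq_len(nrow(segs))) {
    idx <- segs$start_idx[i]:segs$end_idx[i]
    match0 <- mean(out$haps[["1"]][idx, 1] == truth[idx, 1])
    expect_gte(match0, 0.5)
  }
  # re-detecting anchors on the output and re-applying changes nothing
  segs_re <- segs
  segs_re$hap <- vapply(seq_len(nrow(blocks)), function(i) {
    idx <- blocks$from[i]:blocks$to[i]
    idx <- idx[truth[idx, 1] != truth[idx, 2]]
    as.integer(mean(out$haps[["1"]][idx, 1] != truth[idx, 1]) > 0.5)
  }, 1L)
  out2 <- scaffold_phase(out$haps, segs_re, map)
  expect_identical(out2$haps, out$haps)
})

test_that("phasing metrics behave at their reference points", {
  set.seed(43)
  truth <- purrr::map(1:22, ~cbind(rbinom(50, 1, .5), rbinom(50, 1, .5)))
  names(truth) <- as.character(1:22)
  m_id <- phasing_metrics(truth, truth)
  expect_equal(m_id$switch_error_rate, 0)
  expect_equal(m_id$interchromosomal_concordance, 1)
  # one chromosome label swapped out of 22
  inf <- truth
  inf[["7"]] <- inf[["7"]][, 2:1]
  m_one <- phasing_metrics(inf, truth)
  expect_equal(m_one$interchromosomal_concordance, 21 / 22)
  # random phase: switch error near one half
  rand <- purrr::map(truth, function(h) {
    flip <- as.logical(rbinom(nrow(h), 1, 0.5))
    h[flip, ] <- h[flip, 2:1]
    h
  })
  m_rand <- phasing_metrics(rand, truth)
  expect_equal(m_rand$switch_error_rate, 0.5, tolerance = 0.1)
})
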