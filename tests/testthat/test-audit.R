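# Fixed-threshold guideline audits.

test_that("ENCODE minima are inclusive lower bounds", {
  g <- encode_guidelines()
  h3k9 <- g[g$context == "H3K9me3 ChIP-seq", ]
  rna <- g[g$context == "RNA-seq", ]
  dnase <- g[g$context == "DNase-seq", ]
  expect_equal(encode_guideline_check(50e6, h3k9), "meets")
  expect_equal(encode_guideline_check(29e6, rna), "fails")
  expect_equal(encode_guideline_check(20e6, dnase), "meets") # boundary inclusive
  expect_error(encode_guideline_check(-1, rna), "non-negative")
})

test_that("the outlier filter removes impossible profiles and is idempotent", {
  prof <- generate_cistrome_profiles(10, n_outliers = 2, seed = 5)
  expect_equal(nrow(prof), 12)
  kept <- cistrome_outlier_filter(prof)
  expect_equal(nrow(kept), 10)
  expect_equal(attr(kept, "n_removed"), 2)
  again <- cistrome_outlier_filter(kept)
  expect_equal(nrow(again), 10)
  expect_equal(attr(again, "n_removed"), 0)
  # boundary probes
  p <- generate_cistrome_profiles(2, seed = 1)
  p$FASTQC <- c(120, 35)
  p$UniquelyMappedRatio <- c(0.5, 0.99)
  expect_equal(cistrome_outlier_filter(p)$file_id, p$file_id[[2]])
})

test_that("flags use strictly-above semantics at every threshold", {
  p <- generate_cistrome_profiles(3, seed = 2)
  p$FRiP <- c(0.005, 0.01, 0.011)
  p$UniquelyMappedRatio <- c(0.6, 0.601, 0.8)
  p$PeaksFoldChangeAbove10 <- c(500, 501, 499)
  f <- flag_profile(p)
  expect_equal(f$flag_FRiP, c(FALSE, FALSE, TRUE)) # boundary 0.01 is bad
  expect_equal(f$flag_UniquelyMappedRatio, c(FALSE, TRUE, TRUE))
  expect_equal(f$flag_PeaksFoldChangeAbove10, c(FALSE, TRUE, FALSE))
  expect_error(flag_profile(p[, setdiff(names(p), "PBC")]), "PBC")
})

test_that("raising any metric never turns a good flag bad", {
  set.seed(6)
  p <- generate_cistrome_profiles(50, seed = 6)
  f0 <- flag_profile(p)
  for (m in names(cistrome_thresholds())) {
    p2 <- p
    p2[[m]] <- p2[[m]] + abs(rnorm(50))
    f2 <- flag_profile(p2)
    expect_true(all(f2[[paste0("flag_", m)]] >= f0[[paste0("flag_", m)]]))
  }
})

test_that("other-flag counting excludes the focal metric", {
  p <- generate_cistrome_profiles(6, seed = 3)
  thr <- cistrome_thresholds()
  # file 1: metrics 2 and 3 bad, others good
  for (m in names(thr)) p[[m]] <- thr[[m]] * 1.5 + 1
  p$UniquelyMappedRatio <- pmin(p$UniquelyMappedRatio, 0.99)
  p$PBC <- pmin(p$PBC, 0.99)
  p$PeaksUnionDHSRatio <- pmin(p$PeaksUnionDHSRatio, 0.99)
  p$UniquelyMappedRatio[1] <- 0.5
  p$PBC[1] <- 0.5
  f <- flag_profile(p)
  ofa <- other_flag_analysis(f)
  g <- ofa$groups
  # focal FASTQC sees two bad other flags for file 1
  expect_true(any(g$metric == "FASTQC" & g$n_bad_other == 2 & g$n == 1))
  # focal PBC excludes its own bad flag: one bad other
  expect_true(any(g$metric == "PBC" & g$n_bad_other == 1 & g$n == 1))
  # n_bad_other stays within 0..5 and own-flag bookkeeping is conserved
  expect_true(all(g$n_bad_other >= 0 & g$n_bad_other <= 5))
})

test_that("an all-good corpus gives degenerate NA correlations", {
  p <- generate_cistrome_profiles(5, seed = 4)
  thr <- cistrome_thresholds()
  for (m in names(thr)) p[[m]] <- thr[[m]] * 1.2 + 0.01
  p$UniquelyMappedRatio <- 0.95
  p$PBC <- 0.97
  p$PeaksUnionDHSRatio <- 0.9
  ofa <- other_flag_analysis(p)
  expect_true(all(ofa$groups$n_bad_other == 0))
  expect_true(all(is.na(ofa$correlations$pearson)))
})

test_that("monotone badness drives negative metric correlations", {
  p <- generate_cistrome_profiles(500, noise = 0, seed = 7)
  ofa <- other_flag_analysis(p)
  expect_true(all(ofa$correlations$spearman < -0.8))
  expect_true(all(ofa$correlations$pearson < 0))
})

test_that("pairwise correlations form a symmetric unit-diagonal matrix", {
  p <- generate_cistrome_profiles(200, seed = 8)
  m <- pairwise_metric_correlations(p)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 6))
  # duplicated metric column correlates perfectly
  p2 <- p
  p2$FRiP <- p2$FASTQC
  m2 <- pairwise_metric_correlations(p2)
  expect_equal(m2["FRiP", "FASTQC"], 1)
  # independent metrics: off-diagonals near zero at n = 10,000
  pi <- generate_cistrome_profiles(10000, model = "independent", seed = 9)
  mi <- pairwise_metric_correlations(pi)
  expect_lt(max(abs(mi[upper.tri(mi)])), 0.05)
})
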