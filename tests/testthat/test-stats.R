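# Rank-test, FDR and auROC primitives.

test_that("small tie-free samples take the exact enumeration branch", {
  mw <- mann_whitney(c(3, 4), c(1, 2))
  expect_equal(mw$method, "exact")
  expect_equal(mw$U, 4)
  expect_equal(mw$p, 1 / 3)
  # identical constant samples: no separation
  expect_equal(mann_whitney(c(5, 5, 5), c(5, 5, 5))$p, 1)
  # insufficient data signals an NA evaluation
  expect_null(mann_whitney(3, c(1, 2)))
})

test_that("exact branch matches wilcox.test's exact distribution", {
  set.seed(21)
  for (i in 1:50) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- sample.int(1000, n1 + n2) / 7 # tie-free
    mw <- mann_whitney(x[1:n1], x[-(1:n1)])
    ref <- suppressWarnings(stats::wilcox.test(x[1:n1], x[-(1:n1)], exact = TRUE))
    expect_equal(mw$method, "exact")
    expect_equal(mw$p, ref$p.value, tolerance = 1e-12)
    expect_equal(mw$U, unname(ref$statistic))
  }
})

test_that("the corrected normal approximation matches the reference", {
  set.seed(22)
  for (i in 1:200) {
    n1 <- sample(8:25, 1)
    n2 <- sample(8:25, 1)
    x <- rnorm(n1)
    y <- rnorm(n2, mean = runif(1, -1, 1))
    mw <- mann_whitney(x, y)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    expect_equal(mw$method, "normal")
    expect_lt(abs(mw$p - ref$p.value), 1e-8)
  }
  # tie-heavy ordinal data: tie-corrected approximation, still matches
  for (i in 1:50) {
    x <- sample(0:2, 15, replace = TRUE)
    y <- sample(0:2, 15, replace = TRUE)
    if (length(unique(c(x, y))) == 1) next
    mw <- mann_whitney(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_lt(abs(mw$p - ref$p.value), 1e-8)
  }
})

test_that("BH adjustment reproduces the step-up closed form", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH matches p.adjust and keeps its order properties", {
  set.seed(23)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_lt(max(abs(q - stats::p.adjust(p, "BH"))), 1e-10)
    expect_true(all(q >= p - 1e-15))
    # monotone in sorted p
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  # idempotent on already-adjusted monotone inputs
  q <- bh_adjust(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(bh_adjust(q), q)
  # NA passes through without inflating m
  expect_equal(bh_adjust(c(0.005, NA, 0.1)), c(0.01, NA, 0.1))
})

test_that("orientation-max auROC matches brute-force pair counting", {
  expect_equal(orientation_max_auroc(c(1, 2, 3, 4), c("low", "high", "low", "high")), 0.75)
  expect_equal(orientation_max_auroc(rep(1, 6), rep(c("high", "low"), 3)), 0.5)
  # perfectly anti-separating feature: 1.0 via inversion
  expect_equal(orientation_max_auroc(c(5, 6, 1, 2), c("low", "low", "high", "high")), 1)
  set.seed(24)
  for (i in 1:300) {
    n1 <- sample(2:15, 1)
    n2 <- sample(2:15, 1)
    v <- sample(1:8, n1 + n2, replace = TRUE) # ties likely
    lab <- c(rep("high", n1), rep("low", n2))
    a <- orientation_max_auroc(v, lab)
    expect_lt(abs(a - auroc_pairs_oracle(v, lab)), 1e-12)
    expect_gte(a, 0.5)
    # negation invariance
    expect_equal(orientation_max_auroc(-v, lab), a)
    # Mann-Whitney identity under the high-positive orientation
    u <- mann_whitney(v[lab == "high"], v[lab == "low"])
    if (!is.null(u)) {
      a1 <- u$U / (n1 * n2)
      expect_lt(abs(max(a1, 1 - a1) - a), 1e-12)
    }
  }
})

test_that("auROC estimates recover the analytic normal-shift value", {
  set.seed(25)
  d <- sqrt(2)
  est <- replicate(5, {
    v <- c(rnorm(2000, d), rnorm(2000))
    orientation_max_auroc(v, rep(c("high", "low"), each = 2000))
  })
  expect_lt(abs(mean(est) - pnorm(1)), 0.01)
})

test_that("the correlation battery handles the three coefficients and ties", {
  x <- 1:10
  expect_equal(correlation_battery(x, 2 * x + 1)[["pearson"]], 1)
  expect_equal(correlation_battery(x, -x^3)[["spearman"]], -1)
  expect_equal(correlation_battery(c(1, 2, 3), c(1, 3, 2))[["kendall"]], 1 / 3)
  expect_true(all(is.na(correlation_battery(c(1, 1, 1), c(1, 2, 3)))))
  expect_true(is.na(correlation_battery(c(1, 2), c(1, 2))[["pearson"]]))
})
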