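# The CART guideline trees.

test_that("Gini impurity follows the two-class closed form", {
  expect_equal(gini(c(5, 5)), 0.5)
  expect_equal(gini(c(10, 0)), 0)
  expect_equal(gini(c(3, 1)), 0.375)
  expect_error(gini(c(0, 0)), "empty")
})

test_that("best_split finds the midpoint threshold maximizing Gini decrease", {
  d <- tibble::tibble(x = c(1, 2, 3, 4))
  s <- best_split(d, c("low", "low", "high", "high"), "x")
  expect_equal(s$threshold, 2.5)
  expect_equal(s$decrease, 0.5)
  # pure node: nothing to do
  expect_null(best_split(d, rep("high", 4), "x"))
  # constant feature: no candidates
  expect_null(best_split(tibble::tibble(x = rep(1, 4)), c("high", "low", "high", "low"), "x"))
})

test_that("fitted trees match the brute-force recursive oracle", {
  set.seed(31)
  for (i in 1:300) {
    nr <- sample(4:12, 1)
    d <- tibble::tibble(a = runif(nr), b = runif(nr), c = runif(nr))
    lab <- ifelse(runif(nr) < 0.5, "high", "low")
    if (length(unique(lab)) < 2) lab[1] <- setdiff(c("high", "low"), lab[1])
    tr <- fit_tree(d, lab, max_depth = 2, features = c("a", "b", "c"))
    expect_lt(
      abs(tree_total_decrease(tr) - oracle_total_decrease(d, lab, c("a", "b", "c"), 2)),
      1e-12
    )
  }
})

test_that("separable and XOR patterns fit to perfect training accuracy", {
  d <- tibble::tibble(x = c(1, 2, 3, 4))
  lab <- c("low", "low", "high", "high")
  t1 <- fit_tree(d, lab)
  expect_equal(glance(t1)$depth, 1)
  expect_equal(training_accuracy(t1, d, lab), 1)
  # XOR needs the zero-decrease root split
  dx <- tibble::tibble(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
  lx <- c("low", "high", "high", "low")
  tx <- fit_tree(dx, lx, max_depth = 2)
  expect_equal(glance(tx)$depth, 2)
  expect_equal(training_accuracy(tx, dx, lx), 1)
  # while no single depth-1 split separates it
  s <- best_split(dx, lx, c("a", "b"))
  expect_equal(s$decrease, 0)
})

test_that("tree structure respects conservation, depth and determinism", {
  set.seed(32)
  for (i in 1:20) {
    nr <- sample(10:30, 1)
    d <- tibble::tibble(a = runif(nr), b = runif(nr), c = round(runif(nr), 1))
    lab <- ifelse(runif(nr) < 0.5, "high", "low")
    if (length(unique(lab)) < 2) lab[1] <- setdiff(c("high", "low"), lab[1])
    tr <- fit_tree(d, lab, max_depth = 3, features = c("a", "b", "c"))
    nodes <- tidy(tr)
    expect_lte(max(nodes$depth), 3)
    for (id in nodes$node[!nodes$leaf]) {
      kids <- nodes[nodes$parent == id & !is.na(nodes$parent), ]
      parent <- nodes[nodes$node == id, ]
      expect_equal(sum(kids$samples), parent$samples)
      expect_equal(sum(kids$n_high), parent$n_high)
      expect_equal(sum(kids$n_low), parent$n_low)
    }
    # accuracy never below the majority baseline
    expect_gte(
      training_accuracy(tr, d, lab),
      max(mean(lab == "high"), mean(lab == "low"))
    )
    # row order must not matter
    perm <- sample.int(nr)
    tr2 <- fit_tree(d[perm, ], lab[perm], max_depth = 3, features = c("a", "b", "c"))
    expect_equal(tidy(tr2), nodes)
  }
})

test_that("single-class input gives a flagged single-leaf tree", {
  d <- tibble::tibble(x = 1:6)
  tr <- fit_tree(d, rep("high", 6))
  expect_true(tr$degenerate)
  expect_equal(glance(tr)$n_leaves, 1)
  expect_equal(apply_tree(tr, list(x = 3)), "high")
  # majority-tie leaf predicts low
  t0 <- fit_tree(tibble::tibble(x = rep(1, 4)), c("high", "high", "low", "low"))
  expect_equal(apply_tree(t0, list(x = 1)), "low")
  expect_equal(training_accuracy(t0, tibble::tibble(x = rep(1, 4)), c("high", "high", "low", "low")), 0.5)
})

test_that("the published H3K4me1 guideline tree classifies the probe files", {
  tree <- h3k4me1_guideline_tree()
  expect_equal(
    apply_tree(tree, list(MAP_SE_multiple = 10.0, LOC_Other_Intron = 30.0)),
    "low"
  )
  expect_equal(
    apply_tree(tree, list(MAP_SE_multiple = 20.0, `TSS_+2500` = 2.0)),
    "high"
  )
  expect_equal(
    apply_tree(tree, list(MAP_SE_multiple = 20.0, `TSS_+2500` = 3.0, `TSS_+500` = 3.0)),
    "low"
  )
  # missing tested feature errors with its name
  expect_error(
    apply_tree(tree, list(MAP_SE_multiple = 10.0)),
    "LOC_Other_Intron"
  )
  nodes <- tidy(tree)
  expect_equal(sum(!nodes$leaf), 4)
  expect_equal(sum(nodes$leaf), 5)
  expect_equal(nodes$samples[nodes$node == 1], 30)
})

test_that("JSON export and import are a lossless round trip", {
  set.seed(33)
  d <- tibble::tibble(a = runif(20), b = runif(20))
  lab <- rep(c("high", "low"), 10)
  tr <- fit_tree(d, lab, max_depth = 3, features = c("a", "b"))
  path <- tempfile(fileext = ".json")
  export_tree_json(tr, path)
  back <- import_tree_json(path)
  expect_equal(tidy(back), tidy(tr))
  expect_equal(
    predict(back, d),
    predict(tr, d)
  )
})

test_that("DOT output annotates split nodes only with the test line", {
  tr <- fit_tree(
    tibble::tibble(x = c(1, 2, 3, 4)), c("low", "low", "high", "high")
  )
  dot <- export_tree_dot(tr)
  lines <- strsplit(dot, "\n")[[1]]
  leaf_lines <- grep("predicted class = (high|low)\"", lines, value = TRUE)
  expect_length(grep("<=", lines[grepl("label=", lines)]), 1) # root only
  expect_true(any(grepl("samples = 4", lines)))
  expect_true(grepl("->", dot))
})
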