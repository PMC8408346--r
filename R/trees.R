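# Depth-limited binary CART on the Gini criterion, grown greedily with
# exhaustive threshold search. Written against the usual CART conventions:
# the left branch takes value <= threshold, node prediction is the majority
# class (ties flagged low), candidate thresholds sit at midpoints of
# consecutive distinct sorted values.

#' Gini impurity of a two-class node
#'
#' @param counts integer vector `c(n_high, n_low)`
#' @return `1 - sum((counts / n)^2)`, in `[0, 0.5]`.
#' @export
#' @examples
#' gini(c(5, 5)) # 0.5
#' gini(c(3, 1)) # 0.375
gini <- function(counts) {
  if (length(counts) != 2 || any(counts < 0)) abort("counts must be c(n_high, n_low) >= 0")
  n <- sum(counts)
  if (n == 0) abort("empty node has no impurity")
  1 - sum((counts / n)^2)
}

# Split goodness is compared exactly: for child counts (pl, ql | pr, qr)
# the weighted Gini decrease is, up to node constants, the fraction
#   A / D  with  A = (pl^2 + ql^2) * nr + (pr^2 + qr^2) * nl,  D = nl * nr,
# all integers, so candidate splits are ranked by integer cross
# multiplication with no floating-point ties (exact for nodes up to ~1,500
# files, far beyond the subset sizes this is used at).

# best threshold for one feature; returns list(threshold, decrease, a, d)
.best_split_feature <- function(v, pos, parent_gini) {
  o <- order(v)
  v <- v[o]
  pos <- pos[o]
  n <- length(v)
  boundary <- which(v[-n] < v[-1]) # split after index i
  if (length(boundary) == 0) {
    return(NULL)
  }
  cp <- cumsum(pos)
  nl <- boundary
  pl <- cp[boundary]
  ql <- nl - pl
  nr <- n - nl
  pr <- cp[n] - pl
  qr <- nr - pr
  a <- (pl^2 + ql^2) * nr + (pr^2 + qr^2) * nl
  d <- nl * nr
  # first index attaining the exact maximum of a/d -> smallest threshold
  best <- 1L
  for (i in seq_along(a)[-1]) {
    if (a[i] * d[best] > a[best] * d[i]) best <- i
  }
  dec <- parent_gini -
    (nl[best] / n) * (1 - (pl[best] / nl[best])^2 - (ql[best] / nl[best])^2) -
    (nr[best] / n) * (1 - (pr[best] / nr[best])^2 - (qr[best] / nr[best])^2)
  list(
    threshold = (v[boundary[best]] + v[boundary[best] + 1]) / 2,
    decrease = dec, a = a[best], d = d[best]
  )
}

#' Best Gini split of a node
#'
#' Exhaustive search over features and candidate thresholds (midpoints of
#' consecutive distinct sorted values) for the split maximizing the
#' weighted Gini decrease. Ties break deterministically to the lowest
#' feature index (canonical feature order), then the smallest threshold.
#' Features with missing values in the node are not split candidates.
#' Returns `NULL` for a pure node or when every usable feature is
#' constant; a zero-decrease split on an impure node is allowed, matching
#' standard CART behaviour.
#'
#' @param data tibble/data.frame of numeric feature columns
#' @param labels `"high"`/`"low"` labels, one per row
#' @param features columns to consider, in tie-break priority order
#'   (default: canonical order of those present)
#' @return List `feature`, `threshold`, `decrease`, or `NULL`.
#' @export
best_split <- function(data, labels, features = NULL) {
  if (is.null(features)) {
    features <- intersect(feature_names(), names(data))
    if (length(features) == 0) features <- names(data)
  }
  pos <- labels == "high"
  counts <- c(sum(pos), sum(!pos))
  parent_gini <- gini(counts)
  if (parent_gini == 0) {
    return(NULL)
  }
  best <- NULL
  for (f in features) {
    v <- data[[f]]
    if (!is.numeric(v) || anyNA(v)) next
    cand <- .best_split_feature(v, pos, parent_gini)
    if (is.null(cand)) next
    # exact fraction comparison; earlier feature wins ties
    if (is.null(best) || cand$a * best$d > best$a * cand$d) {
      best <- list(
        feature = f, threshold = cand$threshold,
        decrease = cand$decrease, a = cand$a, d = cand$d
      )
    }
  }
  if (is.null(best)) {
    return(NULL)
  }
  best[c("feature", "threshold", "decrease")]
}

.majority_class <- function(counts) {
  # tie -> low: conservative call for quality control
  if (counts[[1]] > counts[[2]]) "high" else "low"
}

.grow_node <- function(data, labels, features, depth, max_depth) {
  counts <- c(sum(labels == "high"), sum(labels == "low"))
  node <- list(
    samples = length(labels),
    samples_by_class = counts,
    predicted_class = .majority_class(counts),
    gini = gini(counts),
    leaf = TRUE
  )
  if (depth >= max_depth || node$gini == 0) {
    return(node)
  }
  split <- best_split(data, labels, features)
  if (is.null(split)) {
    return(node)
  }
  go_left <- data[[split$feature]] <= split$threshold
  node$leaf <- FALSE
  node$feature <- split$feature
  node$threshold <- split$threshold
  node$decrease <- split$decrease
  node$left <- .grow_node(data[go_left, , drop = FALSE], labels[go_left], features, depth + 1, max_depth)
  node$right <- .grow_node(data[!go_left, , drop = FALSE], labels[!go_left], features, depth + 1, max_depth)
  node
}

#' Fit a guideline decision tree
#'
#' Grows a binary CART classifier of the quality class from feature
#' columns, greedy on Gini decrease, to at most `max_depth` splits deep.
#' There is no pruning and no minimum leaf size beyond 1, so small leaves
#' are kept for interpretability. A single-class input yields a degenerate
#' single-leaf tree, flagged in the result.
#'
#' @param data tibble of numeric feature columns (one row per file)
#' @param labels `"high"`/`"low"` labels, one per row
#' @param max_depth maximum number of splits on any root-to-leaf path
#'   (default 3)
#' @param features candidate split columns in tie-break priority order
#' @return A `qc_tree` object.
#' @export
fit_tree <- function(data, labels, max_depth = 3, features = NULL) {
  if (nrow(data) < 2) abort("need at least 2 rows to fit a tree")
  if (length(labels) != nrow(data)) abort("labels must match rows")
  if (!all(labels %in% c("high", "low"))) abort("labels must be 'high'/'low'")
  if (is.null(features)) {
    features <- intersect(feature_names(), names(data))
    if (length(features) == 0) features <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  degenerate <- length(unique(labels)) == 1
  root <- .grow_node(data[, features, drop = FALSE], labels, features, 0, max_depth)
  structure(
    list(
      root = root, max_depth = max_depth, features = features,
      degenerate = degenerate
    ),
    class = "qc_tree"
  )
}

.descend <- function(node, row) {
  while (!node$leaf) {
    v <- row[[node$feature]]
    if (is.null(v) || is.na(v)) {
      abort(paste0("cannot classify: missing value for feature ", node$feature))
    }
    node <- if (v <= node$threshold) node$left else node$right
  }
  node$predicted_class
}

#' Classify a feature vector with a guideline tree
#'
#' Descends the tree taking the left branch when the tested feature value
#' is less than or equal to the node threshold, and returns the leaf's
#' predicted class. A missing value at a tested feature is an error naming
#' the feature.
#'
#' @param tree a `qc_tree`
#' @param vector a one-row tibble, named list or named vector of feature
#'   values
#' @return `"high"` or `"low"`.
#' @export
apply_tree <- function(tree, vector) {
  if (is.data.frame(vector)) {
    stopifnot(nrow(vector) == 1)
    vector <- as.list(vector)
  }
  .descend(tree$root, as.list(vector))
}

#' @export
predict.qc_tree <- function(object, newdata, ...) {
  vapply(
    seq_len(nrow(newdata)),
    function(i) apply_tree(object, newdata[i, , drop = FALSE]),
    character(1)
  )
}

#' Training-set accuracy of a tree
#'
#' @param tree a `qc_tree`
#' @param data feature tibble
#' @param labels `"high"`/`"low"` labels
#' @return Fraction of rows classified to their own label.
#' @export
training_accuracy <- function(tree, data, labels) {
  mean(predict(tree, data) == labels)
}

.tree_nodes <- function(node, id = 1L, depth = 0L, parent = NA_integer_) {
  nd <- node
  row <- tibble(
    node = id, parent = parent, depth = depth, leaf = nd$leaf,
    samples = nd$samples,
    n_high = nd$samples_by_class[[1]], n_low = nd$samples_by_class[[2]],
    predicted_class = nd$predicted_class, gini = nd$gini,
    feature = if (nd$leaf) NA_character_ else nd$feature,
    threshold = if (nd$leaf) NA_real_ else nd$threshold
  )
  if (node$leaf) {
    return(row)
  }
  left <- .tree_nodes(node$left, id * 2L, depth + 1L, id)
  right <- .tree_nodes(node$right, id * 2L + 1L, depth + 1L, id)
  bind_rows(row, left, right)
}

#' @rdname fit_tree
#' @param x,object a `qc_tree`
#' @param ... unused
#' @method tidy qc_tree
#' @export
tidy.qc_tree <- function(x, ...) {
  .tree_nodes(x$root)
}

#' @rdname fit_tree
#' @method glance qc_tree
#' @export
glance.qc_tree <- function(x, ...) {
  nodes <- tidy(x)
  tibble(
    n_samples = x$root$samples,
    n_nodes = nrow(nodes),
    n_leaves = sum(nodes$leaf),
    depth = max(nodes$depth),
    max_depth = x$max_depth,
    degenerate = x$degenerate
  )
}

#' @export
print.qc_tree <- function(x, ...) {
  nodes <- tidy(x)
  cat("<qc_tree> depth ", max(nodes$depth), ", ", sum(nodes$leaf),
    " leaves, ", x$root$samples, " training files\n",
    sep = ""
  )
  show_node <- function(node, indent) {
    pad <- strrep("  ", indent)
    lab <- paste0(
      "[", node$samples_by_class[[1]], " high, ",
      node$samples_by_class[[2]], " low] -> ", node$predicted_class
    )
    if (node$leaf) {
      cat(pad, "* ", lab, "\n", sep = "")
    } else {
      cat(pad, node$feature, " <= ", signif(node$threshold, 6), "  ", lab, "\n", sep = "")
      show_node(node$left, indent + 1)
      show_node(node$right, indent + 1)
    }
  }
  show_node(x$root, 0)
  invisible(x)
}
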