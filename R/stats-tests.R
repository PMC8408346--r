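# Rank-based primitives: Wilcoxon-Mann-Whitney test, Benjamini-Hochberg
# step-up adjustment, orientation-maximized auROC, correlation battery.

# U statistic for x (treated as "positive") vs y, ties counted 1/2
.u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Wilcoxon-Mann-Whitney test
#'
#' Two-sided rank-sum test of a location difference between the feature
#' values of high- and low-quality files. For small tie-free samples
#' (`n_high + n_low <= 12`) the exact permutation null of the U statistic
#' is enumerated; otherwise the normal approximation with tie correction
#' and continuity correction is used. Ordinal features therefore always
#' take the tie-corrected approximation.
#'
#' @param values_high numeric values of the high-quality class
#' @param values_low numeric values of the low-quality class
#' @param exact_max largest total sample size for exact enumeration
#'   (default 12)
#' @return List with elements `U` (high vs low), `p` (two-sided),
#'   `method` (`"exact"` or `"normal"`). Returns `NULL` when either class
#'   has fewer than 2 non-missing values (the caller records an
#'   NA evaluation).
#' @export
#' @examples
#' mann_whitney(c(3, 4), c(1, 2))$p # 1/3 by exact enumeration
mann_whitney <- function(values_high, values_low, exact_max = 12) {
  x <- values_high[!is.na(values_high)]
  y <- values_low[!is.na(values_low)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) {
    return(NULL)
  }
  u <- .u_statistic(x, y)
  has_ties <- anyDuplicated(c(x, y)) > 0
  if (!has_ties && n1 + n2 <= exact_max) {
    # enumerate all assignments of n1 "high" slots over the pooled sample
    pool <- c(x, y)
    combos <- combn(n1 + n2, n1)
    r <- rank(pool)
    us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- min(1, sum(abs(us - mu) >= abs(u - mu) - 1e-9) / ncol(combos))
    return(list(U = u, p = p, method = "exact"))
  }
  n <- n1 + n2
  ties <- table(c(x, y))
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(U = u, p = 1, method = "normal"))
  }
  z <- u - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2) # continuity correction
  list(U = u, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts p-values to false-discovery-rate scale: with the p-values sorted
#' ascending, the i-th adjusted value is `min over j >= i of p_(j) * m / j`,
#' capped at 1, and returned in input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (`NA` passes
#'   through and does not count toward `m`)
#' @return Numeric vector of adjusted values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  m <- length(p)
  out <- rep(NA_real_, length(pvalues))
  if (m > 0) {
    o <- order(p)
    adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
    adj <- pmin(1, adj)
    out[ok][o] <- adj
  }
  out
}

# auROC of values as a score for labels, positives = TRUE, ties 1/2
.auroc_one_sided <- function(values, positive) {
  x <- values[positive]
  y <- values[!positive]
  .u_statistic(x, y) / (length(x) * length(y))
}

#' Orientation-maximized auROC
#'
#' Classification power of a feature irrespective of direction: the auROC
#' of the feature as a score for the high-quality class is computed with
#' the true labels and with the inverted labels, and the larger of the two
#' is returned. Equivalent to `max(a, 1 - a)`, so always in `[0.5, 1]`.
#' Tied high/low pairs count one half concordant (the Mann-Whitney
#' identity `auROC = U / (n_high * n_low)` holds exactly).
#'
#' @param values numeric feature values (`NA` dropped with its label)
#' @param labels vector of `"high"` / `"low"` class labels
#' @return auROC in `[0.5, 1]`, or `NA` if either class is empty after
#'   `NA` removal.
#' @export
orientation_max_auroc <- function(values, labels) {
  ok <- !is.na(values)
  values <- values[ok]
  labels <- labels[ok]
  pos <- labels == "high"
  if (sum(pos) == 0 || sum(!pos) == 0) {
    return(NA_real_)
  }
  a <- .auroc_one_sided(values, pos)
  max(a, 1 - a)
}

#' Correlation battery
#'
#' Pearson, Spearman and/or Kendall (tau-b, tie-corrected) correlation
#' coefficients after pairwise removal of missing values.
#'
#' @param x,y numeric vectors of equal length
#' @param methods subset of `c("pearson", "spearman", "kendall")`
#' @return Named numeric vector of coefficients in `[-1, 1]`; `NA` when
#'   fewer than 3 complete pairs remain or a vector has zero variance.
#' @export
correlation_battery <- function(x, y, methods = c("pearson", "spearman", "kendall")) {
  methods <- match.arg(methods, several.ok = TRUE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  vapply(setNames(methods, methods), function(m) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    cor(x, y, method = m)
  }, numeric(1))
}
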