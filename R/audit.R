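# Fixed-threshold guideline audit: ENCODE numeric minima and the Cistrome
# six-flag system.

#' ENCODE numeric guideline table
#'
#' The published per-assay minima: ChIP-seq targeting the broad mark
#' H3K9me3 wants at least 45 million aligned reads, RNA-seq 30 million
#' aligned reads, DNase-seq 20 million uniquely mapped reads, and ChIP-seq
#' useable fragments at least 45 million (broad peaks) or 20 million
#' (narrow peaks). Editable: pass your own tibble of the same shape to the
#' audit functions.
#'
#' @return Tibble `context`, `metric`, `minimum`.
#' @export
encode_guidelines <- function() {
  tibble(
    context = c(
      "H3K9me3 ChIP-seq", "RNA-seq", "DNase-seq",
      "broad-peak ChIP-seq", "narrow-peak ChIP-seq"
    ),
    metric = c(
      "aligned_reads", "aligned_reads", "uniquely_mapped_reads",
      "useable_fragments", "useable_fragments"
    ),
    minimum = c(45e6, 30e6, 20e6, 45e6, 20e6)
  )
}

#' Check a metric value against an ENCODE guideline
#'
#' Guideline minima are stated as minimal values, so the comparison is
#' inclusive: a file meets the guideline when `value >= minimum`.
#'
#' @param value observed metric value (non-negative count)
#' @param guideline one row of [encode_guidelines()] (or a compatible
#'   list with a `minimum` field)
#' @return `"meets"` or `"fails"`.
#' @export
#' @examples
#' g <- encode_guidelines()[1, ] # H3K9me3 ChIP-seq, 45M aligned reads
#' encode_guideline_check(50e6, g) # meets
encode_guideline_check <- function(value, guideline) {
  if (is.na(value) || value < 0) abort("metric value must be a non-negative number")
  if (guideline$minimum <= 0) abort("guideline minimum must be positive")
  if (value >= guideline$minimum) "meets" else "fails"
}

#' Default Cistrome flag thresholds
#'
#' A metric flags a file as good quality only when strictly above its
#' threshold. `FASTQC` is the raw-sequence median quality score in score
#' units (threshold 25); the caption-style 0.25 fraction scale can be set
#' via this argument wherever thresholds are taken.
#'
#' @return Named numeric vector over the six metrics.
#' @export
cistrome_thresholds <- function() {
  c(
    FASTQC = 25, UniquelyMappedRatio = 0.6, PBC = 0.8,
    FRiP = 0.01, PeaksUnionDHSRatio = 0.7, PeaksFoldChangeAbove10 = 500
  )
}

.cistrome_metrics <- function() names(cistrome_thresholds())

#' Remove implausible Cistrome profiles
#'
#' Profiles with a FastQC median quality score above 100 or a uniquely
#' mapped ratio above 1 are physically impossible and removed before any
#' audit. Idempotent; the number removed is attached as attribute
#' `n_removed`.
#'
#' @param profiles tibble with columns `file_id` and the six metrics
#' @return Filtered tibble.
#' @export
cistrome_outlier_filter <- function(profiles) {
  keep <- profiles$FASTQC <= 100 & profiles$UniquelyMappedRatio <= 1
  out <- profiles[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Flag a profile against the six Cistrome thresholds
#'
#' Strictly-above comparisons: a metric exactly at its threshold flags
#' bad. Monotone by construction - raising a metric can only turn a bad
#' flag good.
#'
#' @param profiles tibble with the six metric columns (extra columns pass
#'   through)
#' @param thresholds named numeric vector as [cistrome_thresholds()]
#' @return `profiles` with added logical flag columns `flag_<metric>`
#'   (`TRUE` = good), `n_bad` (count of bad flags) per file.
#' @export
flag_profile <- function(profiles, thresholds = cistrome_thresholds()) {
  missing <- setdiff(.cistrome_metrics(), names(profiles))
  if (length(missing) > 0) {
    abort(paste0("profiles missing metric(s): ", paste(missing, collapse = ", ")))
  }
  if (anyNA(profiles[.cistrome_metrics()])) abort("metrics must not be NA")
  for (m in .cistrome_metrics()) {
    profiles[[paste0("flag_", m)]] <- profiles[[m]] > thresholds[[m]]
  }
  flags <- as.matrix(profiles[paste0("flag_", .cistrome_metrics())])
  profiles$n_bad <- rowSums(!flags)
  profiles
}

#' Feature value versus badness of the other flags
#'
#' The consistency diagnostic of the six-flag system: for each focal
#' metric, profiles are grouped by how many of the *other* five flags
#' indicate low quality (`n_bad_other`, 0-5), the metric's distribution per
#' group is summarised, and the metric is correlated with `n_bad_other`
#' (Pearson, Spearman, Kendall). An informative, consistent metric shows a
#' negative correlation.
#'
#' @param profiles flagged tibble from [flag_profile()] (profiles are
#'   flagged on the fly if needed), at least 3 rows after outlier
#'   filtering
#' @param thresholds named numeric vector as [cistrome_thresholds()]
#' @return List of two tibbles: `groups` (`metric`, `n_bad_other`, `n`,
#'   quartiles `q1`, `median`, `q3`) and `correlations` (`metric`,
#'   `pearson`, `spearman`, `kendall`).
#' @export
other_flag_analysis <- function(profiles, thresholds = cistrome_thresholds()) {
  if (!"n_bad" %in% names(profiles)) profiles <- flag_profile(profiles, thresholds)
  if (nrow(profiles) < 3) abort("need at least 3 profiles")
  res <- purrr::map(.cistrome_metrics(), function(m) {
    own_bad <- !profiles[[paste0("flag_", m)]]
    n_bad_other <- profiles$n_bad - as.integer(own_bad)
    groups <- tibble(value = profiles[[m]], n_bad_other = n_bad_other) %>%
      group_by(.data$n_bad_other) %>%
      summarise(
        n = dplyr::n(),
        q1 = quantile(.data$value, 0.25),
        median = median(.data$value),
        q3 = quantile(.data$value, 0.75),
        .groups = "drop"
      ) %>%
      mutate(metric = m) %>%
      select("metric", "n_bad_other", "n", "q1", "median", "q3")
    cors <- correlation_battery(profiles[[m]], n_bad_other)
    list(
      groups = groups,
      correlations = tibble(
        metric = m, pearson = cors[["pearson"]],
        spearman = cors[["spearman"]], kendall = cors[["kendall"]]
      )
    )
  })
  list(
    groups = purrr::map_dfr(res, "groups"),
    correlations = purrr::map_dfr(res, "correlations")
  )
}

#' Pairwise Pearson correlations of the six metrics
#'
#' @param profiles tibble with the six metric columns, at least 3 rows
#' @return Symmetric 6x6 matrix with unit diagonal; a zero-variance metric
#'   yields an NA row/column.
#' @export
pairwise_metric_correlations <- function(profiles) {
  if (nrow(profiles) < 3) abort("need at least 3 profiles")
  m <- as.matrix(profiles[.cistrome_metrics()])
  keep_var <- apply(m, 2, stats::sd) > 0
  out <- matrix(NA_real_, 6, 6, dimnames = list(.cistrome_metrics(), .cistrome_metrics()))
  out[keep_var, keep_var] <- cor(m[, keep_var, drop = FALSE])
  diag(out) <- 1
  out
}
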