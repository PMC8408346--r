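# Per-subset, per-feature evaluation: discriminative power (rank test +
# BH FDR pooled within a subset group) and classification power
# (orientation-maximized auROC).

#' Evaluate every feature in every subset of one group
#'
#' For each (subset, feature) pair, the high- and low-quality feature
#' values are compared with [mann_whitney()] and scored with
#' [orientation_max_auroc()]. Benjamini-Hochberg adjustment is applied
#' once to the pooled p-values of the whole group (pass
#' `pool = "subset"` to adjust within each subset instead). Pairs where a
#' class has fewer than 2 non-missing values are reported as NA rows and
#' excluded from the BH pool.
#'
#' @param feature_table tibble with `file_id` and feature columns (a
#'   metadata `quality` column is ignored here; labels come via `records`)
#' @param subsets tibble from [build_subsets()], all of one group and
#'   already size-filtered
#' @param records corpus metadata carrying `file_id` and `quality`
#' @param features feature columns to evaluate (default: the 47 canonical
#'   names present in `feature_table`)
#' @param pool `"group"` (default) or `"subset"`: scope of the BH pool
#' @return Tibble with columns `subset_id`, `feature`, `n_high`, `n_low`,
#'   `U`, `p`, `fdr`, `auroc`.
#' @export
evaluate_subset_group <- function(feature_table, subsets, records,
                                  features = NULL, pool = c("group", "subset")) {
  pool <- match.arg(pool)
  if (nrow(subsets) == 0) abort("no subsets to evaluate")
  if (length(unique(subsets$group)) != 1) {
    abort("subsets must all belong to one group")
  }
  if (is.null(features)) {
    features <- intersect(feature_names(), names(feature_table))
  }
  labels <- setNames(records$quality, records$file_id)
  rows <- purrr::map_dfr(seq_len(nrow(subsets)), function(i) {
    ids <- subsets$member_ids[[i]]
    tab <- feature_table %>% filter(.data$file_id %in% ids)
    qual <- labels[tab$file_id]
    purrr::map_dfr(features, function(f) {
      v <- tab[[f]]
      ok <- !is.na(v)
      vh <- v[ok & qual == "high"]
      vl <- v[ok & qual == "low"]
      mw <- mann_whitney(vh, vl)
      tibble(
        subset_id = subsets$subset_id[[i]],
        feature = f,
        n_high = length(vh),
        n_low = length(vl),
        U = if (is.null(mw)) NA_real_ else mw$U,
        p = if (is.null(mw)) NA_real_ else mw$p,
        auroc = orientation_max_auroc(v, qual)
      )
    })
  })
  if (pool == "group") {
    rows$fdr <- bh_adjust(rows$p)
  } else {
    rows <- rows %>%
      group_by(.data$subset_id) %>%
      mutate(fdr = bh_adjust(.data$p)) %>%
      ungroup()
  }
  rows %>% select(
    "subset_id", "feature", "n_high", "n_low", "U", "p", "fdr", "auroc"
  )
}

#' Count subsets where each feature is significant
#'
#' For each feature, the number of subsets whose adjusted value falls
#' strictly below the cutoff, ranked descending (the per-group
#' significance ranking).
#'
#' @param evaluations tibble from [evaluate_subset_group()]
#' @param fdr_cutoff significance cutoff on the FDR scale (the canonical
#'   report uses 0.01, 0.001 and 0.0001)
#' @param top keep only the first `top` features after ranking (default
#'   all)
#' @return Tibble `feature`, `n_significant`, sorted descending with ties
#'   in canonical feature order.
#' @export
count_significant <- function(evaluations, fdr_cutoff = 0.01, top = Inf) {
  out <- evaluations %>%
    group_by(.data$feature) %>%
    summarise(
      n_significant = sum(!is.na(.data$fdr) & .data$fdr < fdr_cutoff),
      .groups = "drop"
    ) %>%
    mutate(.ord = match(.data$feature, feature_names())) %>%
    arrange(desc(.data$n_significant), .data$.ord) %>%
    select(-".ord")
  if (is.finite(top)) out <- head(out, top)
  out
}

#' Mean and median auROC per feature
#'
#' Summarises each feature's classification power across the subsets of a
#' group: arithmetic mean (the headline statistic) and median, ignoring
#' NA evaluations, plus the number of contributing subsets.
#'
#' @param evaluations tibble from [evaluate_subset_group()]
#' @return Tibble `feature`, `mean_auroc`, `median_auroc`, `n_subsets`, in
#'   canonical feature order.
#' @export
mean_auroc_table <- function(evaluations) {
  evaluations %>%
    group_by(.data$feature) %>%
    summarise(
      mean_auroc = mean(.data$auroc, na.rm = TRUE),
      median_auroc = median(.data$auroc, na.rm = TRUE),
      n_subsets = sum(!is.na(.data$auroc)),
      .groups = "drop"
    ) %>%
    mutate(.ord = match(.data$feature, feature_names())) %>%
    arrange(.data$.ord) %>%
    select(-".ord")
}
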