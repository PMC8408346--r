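# Pipeline orchestration: corpus -> features -> subsets -> evaluations ->
# trees -> report bundle, deterministic for a given config + seed.

.safe_name <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' Default pipeline configuration
#'
#' @param groups subset groups to analyse (default `"A"`)
#' @param min_files inclusive minimum subset size (default 10)
#' @param fdr_cutoffs significance cutoffs for the count tables
#' @param tree_depth maximum tree depth (default 3)
#' @return A config list for [run_pipeline()].
#' @export
pipeline_config <- function(groups = "A", min_files = 10,
                            fdr_cutoffs = c(0.01, 0.001, 1e-4),
                            tree_depth = 3) {
  bad <- setdiff(as.character(groups), names(.subset_group_keys))
  if (length(bad) > 0) {
    abort(paste0("unknown subset group(s) in config: ", paste(bad, collapse = ", ")))
  }
  list(
    groups = as.character(groups), min_files = min_files,
    fdr_cutoffs = fdr_cutoffs, tree_depth = tree_depth
  )
}

#' Run the guideline pipeline
#'
#' Takes a labelled corpus (metadata + feature table, either given
#' directly or generated synthetically from blueprints), builds the
#' requested subset groups, evaluates every feature in every surviving
#' subset, fits a guideline tree per subset, and writes the full report
#' bundle under `out_dir`. Deterministic for a given config and seed.
#'
#' @param corpus either a list with tibbles `records` and `features` (as
#'   from [generate_corpus()]), or a list `blueprints`/`effects` to be
#'   passed to [generate_corpus()]
#' @param config list from [pipeline_config()]
#' @param out_dir output directory (created; pass `NULL` to skip writing)
#' @param seed integer seed for the synthetic stage
#' @return Invisibly, a list: `records`, `features`, and per group
#'   `subsets`, `evaluations`, `counts` (one tibble per cutoff), `summary`
#'   and `trees` (tibble with `subset_id`, `accuracy` and a `tree`
#'   list-column).
#' @export
run_pipeline <- function(corpus, config = pipeline_config(), out_dir = NULL,
                         seed = 1L) {
  if (!is.null(corpus$blueprints)) {
    corpus <- generate_corpus(corpus$blueprints, corpus$effects, seed = seed)
  }
  if (is.null(corpus$records) || is.null(corpus$features)) {
    abort("corpus must provide records and features (or blueprints)")
  }
  records <- corpus$records
  features <- corpus$features
  results <- list(records = records, features = features, groups = list())
  for (g in config$groups) {
    subsets <- filter_min_files(build_subsets(records, g), config$min_files)
    if (nrow(subsets) == 0) {
      results$groups[[g]] <- list(subsets = subsets)
      next
    }
    evals <- evaluate_subset_group(features, subsets, records)
    counts <- purrr::map(
      setNames(config$fdr_cutoffs, config$fdr_cutoffs),
      ~ count_significant(evals, .x)
    )
    summary <- mean_auroc_table(evals)
    trees <- purrr::map_dfr(seq_len(nrow(subsets)), function(i) {
      ids <- subsets$member_ids[[i]]
      tab <- features %>% filter(.data$file_id %in% ids)
      labels <- setNames(records$quality, records$file_id)[tab$file_id]
      usable <- intersect(feature_names(), names(tab))
      usable <- usable[colSums(!is.na(tab[usable])) == nrow(tab)]
      fit <- fit_tree(tab[usable], labels, max_depth = config$tree_depth)
      tibble(
        subset_id = subsets$subset_id[[i]],
        accuracy = training_accuracy(fit, tab[usable], labels),
        tree = list(fit)
      )
    })
    results$groups[[g]] <- list(
      subsets = subsets, evaluations = evals, counts = counts,
      summary = summary, trees = trees
    )
  }
  if (!is.null(out_dir)) build_report(results, out_dir, records)
  invisible(results)
}

#' Write the report bundle
#'
#' Lays out the pipeline results as diff-able text: per group a subsets
#' manifest, evaluation table, significance-count tables and auROC
#' summary; per subset its evaluation rows, tree (JSON + DOT) and a
#' markdown summary; plus a markdown index linking every subset. Report
#' files copy pipeline numbers verbatim - nothing is recomputed here.
#'
#' @param results list returned by [run_pipeline()]
#' @param out_dir output directory
#' @param records corpus metadata (for composition summaries)
#' @return `out_dir`, invisibly.
#' @export
build_report <- function(results, out_dir, records = results$records) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(results$features, file.path(out_dir, "feature_table.csv"))
  write_metadata(records, file.path(out_dir, "metadata.csv"))
  index <- c("# Guideline report", "")
  for (g in names(results$groups)) {
    res <- results$groups[[g]]
    gdir <- file.path(out_dir, "reports", g)
    dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
    write_subsets_manifest(res$subsets, file.path(gdir, "subsets.csv"))
    if (is.null(res$evaluations)) next
    miss <- setdiff(res$trees$subset_id, res$evaluations$subset_id)
    if (length(miss) > 0) {
      abort(paste0("trees without evaluations: ", paste(miss, collapse = ", ")))
    }
    readr::write_csv(res$evaluations, file.path(gdir, "evaluations.csv"), na = "NA")
    for (cutoff in names(res$counts)) {
      readr::write_csv(
        res$counts[[cutoff]],
        file.path(gdir, paste0("significance_counts_", cutoff, ".csv")),
        na = "NA"
      )
    }
    readr::write_csv(res$summary, file.path(gdir, "auroc_summary.csv"), na = "NA")
    index <- c(index, paste0("## Group ", g), "")
    for (i in seq_len(nrow(res$subsets))) {
      sid <- res$subsets$subset_id[[i]]
      sdir <- file.path(gdir, .safe_name(sid))
      dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
      ev <- res$evaluations %>% filter(.data$subset_id == sid)
      readr::write_csv(ev, file.path(sdir, "evaluation.csv"), na = "NA")
      ti <- which(res$trees$subset_id == sid)
      tree <- res$trees$tree[[ti]]
      export_tree_json(tree, file.path(sdir, "tree.json"))
      export_tree_dot(tree, file.path(sdir, "tree.dot"))
      comp <- composition_summary(res$subsets[i, ], records)
      top <- ev %>%
        filter(!is.na(.data$fdr)) %>%
        arrange(.data$fdr, desc(.data$auroc)) %>%
        head(5)
      md <- c(
        paste0("# Subset ", sid), "",
        paste0(
          "Files: ", res$subsets$n_files[[i]], " (",
          res$subsets$n_high[[i]], " high / ", res$subsets$n_low[[i]], " low)"
        ),
        paste0("Tree training accuracy: ", round(res$trees$accuracy[[ti]], 4)), "",
        "Top features (by FDR):",
        paste0(
          "- ", top$feature, ": fdr=", signif(top$fdr, 4),
          ", auROC=", round(top$auroc, 3)
        ),
        "",
        "Composition:",
        paste0(
          "- ", comp$parameter, "=", comp$value, ": ",
          comp$n_high, " high / ", comp$n_low, " low"
        )
      )
      writeLines(md, file.path(sdir, "summary.md"))
      index <- c(index, paste0(
        "- [", sid, "](reports/", g, "/", .safe_name(sid),
        "/summary.md): accuracy ", round(res$trees$accuracy[[ti]], 4)
      ))
    }
    index <- c(index, "")
  }
  writeLines(index, file.path(out_dir, "index.md"))
  invisible(out_dir)
}
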