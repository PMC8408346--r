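# Corpus stratification: the five subset groups.
#
# Group 1: organism x assay x run type        (high-level)
# Group 2: organism x assay title x run type  (high-level)
# Group A: assay title x organism x run type x biological sample
# Group B: assay title x organism x run type x protein target
# Group C: assay title x organism x run type x protein target x antibody

.subset_group_keys <- list(
  "1" = c("organism", "assay", "run_type"),
  "2" = c("organism", "assay_title", "run_type"),
  "A" = c("assay_title", "organism", "run_type", "biological_sample"),
  "B" = c("assay_title", "organism", "run_type", "target_protein"),
  "C" = c("assay_title", "organism", "run_type", "target_protein", "antibody")
)

#' Defining metadata fields of a subset group
#'
#' @param group one of `"1"`, `"2"`, `"A"`, `"B"`, `"C"`
#' @return Character vector of metadata column names.
#' @export
subset_group_keys <- function(group) {
  group <- as.character(group)
  if (!group %in% names(.subset_group_keys)) {
    abort(paste0("unknown subset group: ", group, " (expected 1, 2, A, B or C)"))
  }
  .subset_group_keys[[group]]
}

#' Stratify file records into condition subsets
#'
#' Partitions a corpus into subsets sharing all defining metadata values of
#' the requested group. Records lacking any defining field (for example no
#' antibody annotation under group C) belong to no subset of that group.
#' Subset identifiers concatenate the group tag with the key values, giving
#' deterministic output names.
#'
#' @param records tibble from [read_metadata()]
#' @param group one of `"1"`, `"2"`, `"A"`, `"B"`, `"C"`
#' @return Tibble with one row per subset: `subset_id`, `group`, the key
#'   columns, `n_files`, `n_high`, `n_low` and a list-column `member_ids`.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   file_id = paste0("f", 1:4), quality = c("high", "low", "high", "high"),
#'   organism = c("human", "human", "human", "mouse"), assay = "ChIP-seq",
#'   assay_title = "TF ChIP-seq", run_type = "SE"
#' )
#' build_subsets(rec, "1")
build_subsets <- function(records, group) {
  keys <- subset_group_keys(group)
  missing_cols <- setdiff(keys, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "records lack column(s) needed by group ", group, ": ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  records %>%
    filter(dplyr::if_all(all_of(keys), ~ !is.na(.x))) %>%
    group_by(across(all_of(keys))) %>%
    summarise(
      n_files = dplyr::n(),
      n_high = sum(.data$quality == "high"),
      n_low = sum(.data$quality == "low"),
      member_ids = list(.data$file_id),
      .groups = "drop"
    ) %>%
    arrange(across(all_of(keys))) %>%
    mutate(
      group = as.character(group),
      subset_id = paste(
        as.character(group),
        apply(across(all_of(keys)), 1, paste, collapse = "|"),
        sep = "|"
      )
    ) %>%
    select("subset_id", "group", all_of(keys), "n_files", "n_high", "n_low", "member_ids")
}

#' Keep subsets with a minimum number of files
#'
#' @param subsets tibble from [build_subsets()]
#' @param k inclusive minimum size (default 10)
#' @return The filtered tibble, order preserved.
#' @export
filter_min_files <- function(subsets, k = 10) {
  if (k < 1) abort("k must be >= 1")
  subsets %>% filter(.data$n_files >= k)
}

#' Composition of a subset by a secondary parameter
#'
#' Counts subset members per value of a lower-level metadata field, split by
#' quality class: the bias diagnostic for subsets dominated by a few
#' samples, targets or antibodies.
#'
#' @param subset one row of a [build_subsets()] result
#' @param records the corpus metadata tibble
#' @param by one or more of `"biological_sample"`, `"target_protein"`,
#'   `"antibody"`
#' @return Tibble `parameter`, `value`, `n_high`, `n_low`, `n`.
#' @export
composition_summary <- function(subset, records,
                                by = c("biological_sample", "target_protein", "antibody")) {
  by <- intersect(by, names(records))
  members <- records %>% filter(.data$file_id %in% subset$member_ids[[1]])
  purrr::map_dfr(by, function(col) {
    members %>%
      group_by(value = .data[[col]]) %>%
      summarise(
        n_high = sum(.data$quality == "high"),
        n_low = sum(.data$quality == "low"),
        n = dplyr::n(),
        .groups = "drop"
      ) %>%
      mutate(parameter = col) %>%
      select("parameter", "value", "n_high", "n_low", "n")
  })
}

#' Write a subsets manifest
#'
#' @param subsets tibble from [build_subsets()]
#' @param path CSV path
#' @return `path`, invisibly.
#' @export
write_subsets_manifest <- function(subsets, path) {
  readr::write_csv(select(subsets, -"member_ids"), path, na = "NA")
  invisible(path)
}
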