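#' Read per-file experiment metadata
#'
#' Reads a tabular metadata file (TSV or CSV, detected from the header line)
#' describing one sequencing file per row and returns a validated tibble of
#' file records. Curation labels `released`/`revoked` are mapped to the
#' internal quality classes `high`/`low` at this boundary; empty cells become
#' `NA`.
#'
#' @param path path to a delimited text file, or a literal character vector
#'   of lines
#' @return A tibble with columns `file_id`, `quality` (`"high"`/`"low"`),
#'   `organism`, `assay`, `assay_title`, `run_type` (`"SE"`/`"PE"`) and,
#'   when present in the input, `biological_sample`, `target_protein`,
#'   `antibody`.
#' @export
#' @examples
#' lines <- c(
#'   "file_id\tquality\torganism\tassay\tassay_title\trun_type",
#'   "f1\treleased\thuman\tChIP-seq\tHistone ChIP-seq\tSE"
#' )
#' read_metadata(lines)
read_metadata <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  if (length(lines) < 1) abort("metadata input is empty")
  delim <- if (grepl("\t", lines[[1]])) "\t" else ","
  tab <- readr::read_delim(I(paste(lines, collapse = "\n")),
    delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA")
  )
  mandatory <- c("file_id", "quality", "organism", "assay", "assay_title", "run_type")
  missing <- setdiff(mandatory, names(tab))
  if (length(missing) > 0) {
    abort(paste0(
      "metadata is missing mandatory column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  dup <- tab$file_id[duplicated(tab$file_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate file_id in metadata: ", paste(unique(dup), collapse = ", ")))
  }
  qual_map <- c(
    released = "high", revoked = "low",
    high = "high", low = "low"
  )
  bad_q <- setdiff(unique(tab$quality), names(qual_map))
  if (length(bad_q) > 0) {
    abort(paste0("unknown quality label(s): ", paste(bad_q, collapse = ", ")))
  }
  bad_rt <- setdiff(unique(tab$run_type), c("SE", "PE"))
  if (length(bad_rt) > 0) {
    abort(paste0("run_type must be SE or PE, got: ", paste(bad_rt, collapse = ", ")))
  }
  optional <- c("biological_sample", "target_protein", "antibody")
  tab %>%
    mutate(quality = unname(qual_map[.data$quality])) %>%
    select(all_of(mandatory), any_of(optional)) %>%
    as_tibble()
}

#' Write per-file metadata
#'
#' @param records tibble as returned by [read_metadata()]
#' @param path output path; extension `.tsv` writes tab-separated, anything
#'   else comma-separated
#' @return `path`, invisibly.
#' @export
write_metadata <- function(records, path) {
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(records, path, na = "")
  } else {
    readr::write_csv(records, path, na = "")
  }
  invisible(path)
}
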