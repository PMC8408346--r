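#' Parse a FastQC summary.txt
#'
#' Reads the per-module PASS/WARN/FAIL lines of a FastQC `summary.txt`
#' (tab-separated `STATUS<TAB>Module Name<TAB>filename`) and returns the
#' complete set of raw-read QC flags. Module names are normalized to the
#' canonical `RAW_` feature names (spaces become underscores). Lines naming
#' an unknown module are skipped with a warning; a missing module is an
#' error, because every downstream consumer assumes a complete flag set.
#'
#' @param path path to a `summary.txt`, or a character vector of its lines
#' @return A named character vector of length 12 mapping each `RAW_*`
#'   feature name to `"pass"`, `"warning"` or `"fail"`.
#' @export
#' @examples
#' lines <- paste("PASS", gsub("_", " ", sub("RAW_", "", feature_names("RAW"))),
#'   "x.fastq",
#'   sep = "\t"
#' )
#' parse_fastqc_summary(lines)[["RAW_Basic_Statistics"]]
parse_fastqc_summary <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("FastQC summary is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    abort(paste0("malformed FastQC summary line ", bad[[1]], ": ", lines[[bad[[1]]]]))
  }
  status_map <- c(PASS = "pass", WARN = "warning", FAIL = "fail")
  out <- character(0)
  for (p in parts) {
    status <- toupper(trimws(p[[1]]))
    module <- paste0("RAW_", gsub(" ", "_", trimws(p[[2]])))
    if (!status %in% names(status_map)) {
      abort(paste0("unknown FastQC status: ", p[[1]]))
    }
    if (!module %in% feature_names("RAW")) {
      warn(paste0("skipping unknown FastQC module: ", trimws(p[[2]])))
      next
    }
    out[[module]] <- unname(status_map[[status]])
  }
  missing <- setdiff(feature_names("RAW"), names(out))
  if (length(missing) > 0) {
    abort(paste0(
      "FastQC summary is missing module(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  out[feature_names("RAW")]
}
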