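# Mapping-statistics container: a one-row tibble with run_type and the
# percentage fields of the matching MAP block, values as printed in the log
# (two decimals, 0-100).

.pct <- function(line) {
  m <- regmatches(line, regexpr("\\(?[0-9]+\\.[0-9]+%\\)?", line))
  if (length(m) == 0) abort(paste0("no percentage found in line: ", line))
  as.numeric(gsub("[()%]", "", m))
}

.grab_line <- function(lines, pattern, what) {
  hit <- grep(pattern, lines)
  if (length(hit) == 0) {
    abort(paste0("malformed aligner log: missing '", what, "' (pattern: ", pattern, ")"))
  }
  lines[[hit[[1]]]]
}

#' Validate mapping statistics
#'
#' Checks the conservation invariants of a mapping-statistics row: category
#' percentages sum to 100 within printing tolerance, the overall rate is
#' consistent for single-end data, and all values lie in `[0, 100]`.
#'
#' @param stats one-row tibble from [parse_aligner_log()]
#' @param tol rounding tolerance on percent sums (default 0.02)
#' @return `stats`, invisibly; errors on violation.
#' @export
validate_mapping_stats <- function(stats, tol = 0.02) {
  vals <- unlist(stats[setdiff(names(stats), "run_type")])
  if (any(vals < -tol | vals > 100 + tol)) {
    abort("mapping percentages must lie in [0, 100]")
  }
  if (stats$run_type == "SE") {
    s <- stats$no_mapping + stats$uniquely + stats$multiple
    if (abs(s - 100) > tol) {
      abort(paste0("SE mapping categories sum to ", s, ", expected 100"))
    }
    if (abs(stats$overall - (100 - stats$no_mapping)) > tol) {
      abort("SE overall rate inconsistent with unmapped percentage")
    }
  } else {
    s <- stats$con_no_mapping + stats$con_uniquely + stats$con_multiple
    if (abs(s - 100) > tol) {
      abort(paste0("PE concordant categories sum to ", s, ", expected 100"))
    }
  }
  invisible(stats)
}

#' Parse a Bowtie2 alignment-summary log
#'
#' Extracts the mapping-rate percentages from a Bowtie2 run log (the
#' `--met`-free stderr summary). For single-end runs these are the
#' percentages of reads aligning zero, exactly one, or more than one time,
#' plus the overall alignment rate. For paired-end runs the concordant
#' categories, the discordant-unique rate, and the three rates for mates of
#' pairs that aligned neither concordantly nor discordantly are extracted.
#' Percentages are taken as printed (two decimals).
#'
#' @param path path to a log file, or a character vector of its lines
#' @param run_type `"SE"` or `"PE"`; must match the log structure
#' @return A one-row tibble with `run_type` and, for SE, columns
#'   `no_mapping`, `uniquely`, `multiple`, `overall`; for PE, columns
#'   `con_no_mapping`, `con_uniquely`, `con_multiple`, `dis_uniquely`,
#'   `cod_no_mapping`, `cod_uniquely`, `cod_multiple`, `overall`.
#' @export
parse_aligner_log <- function(path, run_type = c("SE", "PE")) {
  run_type <- match.arg(run_type)
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  if (length(lines) == 0) abort("aligner log is empty")
  overall <- .pct(.grab_line(lines, "overall alignment rate", "overall alignment rate"))
  if (run_type == "SE") {
    if (any(grepl("aligned concordantly", lines))) {
      abort("log reports paired-end categories but run_type is SE")
    }
    stats <- tibble(
      run_type = "SE",
      no_mapping = .pct(.grab_line(lines, "aligned 0 times$", "aligned 0 times")),
      uniquely = .pct(.grab_line(lines, "aligned exactly 1 time$", "aligned exactly 1 time")),
      multiple = .pct(.grab_line(lines, "aligned >1 times$", "aligned >1 times")),
      overall = overall
    )
  } else {
    if (!any(grepl("aligned concordantly", lines))) {
      abort("log lacks the concordant-alignment section expected for PE")
    }
    if (!any(grepl("aligned discordantly", lines))) {
      abort("log lacks the discordant-alignment section expected for PE")
    }
    mates_at <- grep("mates make up the pairs", lines)
    if (length(mates_at) == 0) {
      abort("log lacks the unaligned-pair mates section expected for PE")
    }
    mates <- lines[(mates_at[[1]] + 1):length(lines)]
    stats <- tibble(
      run_type = "PE",
      con_no_mapping = .pct(.grab_line(lines, "aligned concordantly 0 times$", "aligned concordantly 0 times")),
      con_uniquely = .pct(.grab_line(lines, "aligned concordantly exactly 1 time$", "aligned concordantly exactly 1 time")),
      con_multiple = .pct(.grab_line(lines, "aligned concordantly >1 times$", "aligned concordantly >1 times")),
      dis_uniquely = .pct(.grab_line(lines, "aligned discordantly 1 time$", "aligned discordantly 1 time")),
      cod_no_mapping = .pct(.grab_line(mates, "aligned 0 times$", "mates aligned 0 times")),
      cod_uniquely = .pct(.grab_line(mates, "aligned exactly 1 time$", "mates aligned exactly 1 time")),
      cod_multiple = .pct(.grab_line(mates, "aligned >1 times$", "mates aligned >1 times")),
      overall = overall
    )
  }
  validate_mapping_stats(stats)
}
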