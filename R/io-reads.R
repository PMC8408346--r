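# A read set is the minimal carrier for LOC/TSS computation: one anchor per
# mapped read (or per properly oriented pair), where the anchor is the
# strand-aware 5' end in 0-based coordinates (start for "+", end - 1 for
# "-"). Stored as a tibble (chrom, pos, strand) with provenance attributes.

new_read_set <- function(df, provenance = "full", file_id = NA_character_,
                         n_skipped = 0L) {
  stopifnot(all(c("chrom", "pos", "strand") %in% names(df)))
  out <- as_tibble(df[, c("chrom", "pos", "strand")])
  attr(out, "provenance") <- provenance
  attr(out, "file_id") <- file_id
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("read_set", class(out))
  out
}

#' @export
print.read_set <- function(x, ...) {
  cat(
    "<read_set> ", nrow(x), " anchors (", attr(x, "provenance"),
    "), ", attr(x, "n_skipped"), " records skipped\n",
    sep = ""
  )
  NextMethod()
}

#' Read mapped-read anchors from BED6 or SAM/BAM
#'
#' Loads mapped reads and reduces each to its anchor: the strand-aware
#' 5' end in 0-based coordinates. For paired-end alignments
#' (`paired = TRUE`), each properly oriented pair contributes a single
#' anchor at the 5' end of its leftmost (forward-strand) mate. Unmapped
#' records are skipped and counted.
#'
#' @param path a `.bed` (BED6), `.sam` or `.bam` file
#' @param paired treat the alignment file as paired-end (one anchor per
#'   proper pair); ignored for BED input
#' @param file_id optional identifier recorded on the result
#' @return A `read_set` tibble with columns `chrom`, `pos` (0-based),
#'   `strand`, and attributes `provenance`, `file_id`, `n_skipped`.
#' @export
read_reads <- function(path, paired = FALSE, file_id = NA_character_) {
  if (!file.exists(path)) abort(paste0("cannot read alignment input: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    if (length(gr) == 0) abort("no records in BED input")
    strand <- as.character(GenomicRanges::strand(gr))
    if (any(strand == "*")) abort("BED6 input requires a strand column")
    pos <- ifelse(strand == "+",
      GenomicRanges::start(gr) - 1L,
      GenomicRanges::end(gr) - 1L
    )
    rs <- new_read_set(
      tibble(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        pos = as.integer(pos), strand = strand
      ),
      file_id = file_id
    )
    return(rs)
  }
  if (!ext %in% c("sam", "bam")) {
    abort(paste0("unsupported alignment format: .", ext))
  }
  bam <- if (ext == "sam") {
    Rsamtools::asBam(path,
      destination = tempfile(fileext = ""),
      overwrite = TRUE, indexDestination = FALSE
    )
  } else {
    path
  }
  flags <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = "flag"))[[1]]$flag
  n_total <- length(flags)
  if (paired) {
    param <- Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(
        isUnmappedQuery = FALSE, isProperPair = TRUE,
        isMinusStrand = FALSE
      ),
      what = c("rname", "pos", "strand")
    )
    rec <- Rsamtools::scanBam(bam, param = param)[[1]]
    keep <- !is.na(rec$pos)
    df <- tibble(
      chrom = as.character(rec$rname)[keep],
      pos = rec$pos[keep] - 1L, # leftmost mate 5' end, 0-based
      strand = "+"
    )
  } else {
    param <- Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
    )
    ga <- GenomicAlignments::readGAlignments(bam, param = param)
    strand <- as.character(GenomicAlignments::strand(ga))
    df <- tibble(
      chrom = as.character(GenomicAlignments::seqnames(ga)),
      pos = as.integer(ifelse(strand == "+",
        GenomicAlignments::start(ga) - 1L,
        GenomicAlignments::end(ga) - 1L
      )),
      strand = strand
    )
  }
  if (nrow(df) == 0) abort("zero mapped reads in alignment input")
  new_read_set(df, file_id = file_id, n_skipped = n_total - nrow(df))
}

#' Write a read set as BED6
#'
#' Each anchor is written as a width-1 interval so that the strand-aware
#' 5' end survives a round trip through [read_reads()].
#'
#' @param reads a `read_set`
#' @param path output `.bed` path
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  df <- tibble(
    chrom = reads$chrom,
    start = reads$pos,
    end = reads$pos + 1L,
    name = paste0("r", seq_len(nrow(reads))),
    score = 0L,
    strand = reads$strand
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}
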