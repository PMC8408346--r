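# Genome annotation container: chromosome lengths plus transcript models
# (transcripts, exons, CDS) in 1-based closed coordinates, the substrate for
# the nine genomic-localization categories and the TSS bins.

#' Construct a genome annotation
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp)
#' @param transcripts tibble with columns `tx_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (1-based closed intervals)
#' @param exons tibble with columns `tx_id`, `start`, `end`; exon rank is
#'   derived from transcript orientation
#' @param cds optional tibble with columns `tx_id`, `start`, `end`; used to
#'   derive UTRs (may be empty for non-coding annotations)
#' @return A `genome_annotation` object.
#' @export
genome_annotation <- function(chrom_lengths, transcripts, exons,
                              cds = tibble(tx_id = character(), start = integer(), end = integer())) {
  transcripts <- as_tibble(transcripts)
  exons <- as_tibble(exons)
  cds <- as_tibble(cds)
  if (nrow(transcripts) == 0) abort("annotation must contain at least one transcript")
  if (!all(transcripts$chrom %in% names(chrom_lengths))) {
    abort("every transcript chromosome needs a declared length")
  }
  if (any(transcripts$end > chrom_lengths[transcripts$chrom])) {
    abort("transcript extents exceed chromosome lengths")
  }
  ex <- left_join(exons, transcripts, by = "tx_id", suffix = c("", ".tx"))
  if (any(is.na(ex$start.tx))) abort("exon references unknown tx_id")
  if (any(ex$start < ex$start.tx | ex$end > ex$end.tx)) {
    abort("exons must lie within their transcript extent")
  }
  structure(
    list(
      chrom_lengths = chrom_lengths,
      transcripts = transcripts,
      exons = exons,
      cds = cds
    ),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(
    "<genome_annotation> ", length(x$chrom_lengths), " chromosome(s), ",
    nrow(x$transcripts), " transcript(s), ", nrow(x$exons), " exon(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Transcription start sites of an annotation
#'
#' @param annotation a `genome_annotation`
#' @return Tibble `tx_id`, `chrom`, `pos` (0-based TSS coordinate: the
#'   transcript 5' end respecting strand), `strand`.
#' @export
annotation_tss <- function(annotation) {
  tx <- annotation$transcripts
  tibble(
    tx_id = tx$tx_id,
    chrom = tx$chrom,
    pos = as.integer(ifelse(tx$strand == "+", tx$start - 1L, tx$end - 1L)),
    strand = tx$strand
  )
}

#' Write a genome annotation as GFF3
#'
#' Emits gene / mRNA / exon / CDS features with `##sequence-region`
#' pragmas carrying the chromosome lengths.
#'
#' @param annotation a `genome_annotation`
#' @param path output `.gff3` path
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  tx <- annotation$transcripts
  genes <- tx %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  fmt <- function(chrom, src, type, start, end, strand, attrs) {
    paste(chrom, src, type, start, end, ".", strand, ".", attrs, sep = "\t")
  }
  lines <- c(
    "##gff-version 3",
    paste("##sequence-region", names(annotation$chrom_lengths), 1,
      unname(annotation$chrom_lengths)
    ),
    fmt(
      genes$chrom, "seqguide", "gene", genes$start, genes$end, genes$strand,
      paste0("ID=", genes$gene_id)
    ),
    fmt(
      tx$chrom, "seqguide", "mRNA", tx$start, tx$end, tx$strand,
      paste0("ID=", tx$tx_id, ";Parent=", tx$gene_id)
    )
  )
  ex <- left_join(annotation$exons, tx[, c("tx_id", "chrom", "strand")], by = "tx_id")
  lines <- c(lines, fmt(
    ex$chrom, "seqguide", "exon", ex$start, ex$end, ex$strand,
    paste0("Parent=", ex$tx_id)
  ))
  if (nrow(annotation$cds) > 0) {
    cd <- left_join(annotation$cds, tx[, c("tx_id", "chrom", "strand")], by = "tx_id")
    lines <- c(lines, fmt(
      cd$chrom, "seqguide", "CDS", cd$start, cd$end, cd$strand,
      paste0("Parent=", cd$tx_id)
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a genome annotation from GFF3
#'
#' Transcript features (`mRNA`/`transcript`), their `exon` and `CDS`
#' children, and chromosome lengths from `##sequence-region` pragmas are
#' collected into a [genome_annotation()].
#'
#' @param path a GFF3 file
#' @return A `genome_annotation`.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  parent <- vapply(
    as.list(meta$Parent),
    function(p) if (length(p) == 0) NA_character_ else p[[1]], character(1)
  )
  is_tx <- type %in% c("mRNA", "transcript")
  if (!any(is_tx)) abort("GFF3 contains no mRNA/transcript features")
  transcripts <- tibble(
    tx_id = as.character(meta$ID[is_tx]),
    gene_id = parent[is_tx],
    chrom = chrom[is_tx],
    start = GenomicRanges::start(gr)[is_tx],
    end = GenomicRanges::end(gr)[is_tx],
    strand = strand[is_tx]
  )
  pick <- function(t) {
    sel <- type == t
    tibble(
      tx_id = parent[sel],
      start = GenomicRanges::start(gr)[sel],
      end = GenomicRanges::end(gr)[sel]
    )
  }
  # sequence-region pragmas carry the lengths; fall back to observed extents
  pragma <- grep("^##sequence-region", readLines(path), value = TRUE)
  if (length(pragma) > 0) {
    parts <- strsplit(trimws(pragma), "\\s+")
    chrom_lengths <- setNames(
      vapply(parts, function(p) as.integer(p[[4]]), integer(1)),
      vapply(parts, function(p) p[[2]], character(1))
    )
  } else {
    chrom_lengths <- tapply(GenomicRanges::end(gr), chrom, max)
    chrom_lengths <- setNames(as.integer(chrom_lengths), names(chrom_lengths))
  }
  genome_annotation(chrom_lengths, transcripts, pick("exon"), pick("CDS"))
}
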