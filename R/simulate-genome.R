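# Toy genomes and read plans: small annotated chromosomes plus read sets
# planted so that each anchor falls in a known localization category or TSS
# bin - the ground truth for recovery tests of the extraction rules.

#' Generate a toy genome annotation
#'
#' Lays out `n_genes` non-overlapping three-exon transcripts on one
#' chromosome, alternating strands, each with a CDS leaving 5' and 3'
#' UTRs, evenly spaced so that every gene's TSS is well separated from its
#' neighbours. Gene start positions are jittered within their slot for a
#' given seed.
#'
#' @param n_genes number of genes (default 5)
#' @param chrom_length chromosome length in bp (default 2.5e5)
#' @param gene_length transcript span in bp (default 36000). Must be large
#'   enough that exons, introns and UTRs keep territory outside the
#'   promoter window (span > 10x the promoter half-width works with the
#'   default geometry)
#' @param chrom chromosome name
#' @param seed integer seed for the jitter
#' @return A [genome_annotation()].
#' @export
generate_toy_genome <- function(n_genes = 5, chrom_length = 2.5e5,
                                gene_length = 36000, chrom = "chrT", seed = 1L) {
  if (gene_length < 600) abort("gene_length must be at least 600")
  slot <- floor(chrom_length / n_genes)
  margin <- 12000 # promoter + downstream + TSS window clearance
  if (slot < gene_length + margin) {
    abort("cannot pack genes: increase chrom_length or reduce n_genes")
  }
  jitter <- with_local_seed(seed, sample.int(slot - gene_length - margin, n_genes, replace = TRUE))
  start <- (seq_len(n_genes) - 1L) * slot + margin %/% 2L + jitter
  strand <- rep(c("+", "-"), length.out = n_genes)
  u <- gene_length / 10 # exon layout in tenths of the span
  tx <- tibble(
    tx_id = sprintf("tx%02d", seq_len(n_genes)),
    gene_id = sprintf("g%02d", seq_len(n_genes)),
    chrom = chrom,
    start = as.integer(start),
    end = as.integer(start + gene_length - 1L),
    strand = strand
  )
  exon_one <- function(s, lo, hi) {
    tibble(start = as.integer(s + lo * u), end = as.integer(s + hi * u - 1))
  }
  exons <- purrr::map_dfr(seq_len(n_genes), function(i) {
    s <- tx$start[[i]]
    bind_rows(exon_one(s, 0, 2), exon_one(s, 4, 6), exon_one(s, 8, 10)) %>%
      mutate(tx_id = tx$tx_id[[i]])
  })
  # CDS from mid-exon1 to mid-exon3 (in genomic coordinates), leaving UTRs
  cds <- purrr::map_dfr(seq_len(n_genes), function(i) {
    s <- tx$start[[i]]
    tibble(
      tx_id = tx$tx_id[[i]],
      start = as.integer(c(s + 1 * u, s + 4 * u, s + 8 * u)),
      end = as.integer(c(s + 2 * u - 1, s + 6 * u - 1, s + 9 * u - 1))
    )
  })
  genome_annotation(setNames(as.integer(chrom_length), chrom), tx, exons, cds)
}

# exclusive (precedence-resolved) region per category, as GRanges
.exclusive_category_ranges <- function(annotation, promoter_bp = 3000,
                                       downstream_bp = 3000) {
  cats <- loc_category_ranges(annotation, promoter_bp, downstream_bp)
  taken <- GenomicRanges::GRanges()
  out <- list()
  for (nm in names(cats)) {
    red <- GenomicRanges::reduce(cats[[nm]])
    out[[nm]] <- GenomicRanges::setdiff(red, taken, ignore.strand = TRUE)
    taken <- GenomicRanges::reduce(c(taken, red), ignore.strand = TRUE)
  }
  genome <- GenomicRanges::GRanges(
    seqnames = names(annotation$chrom_lengths),
    ranges = IRanges::IRanges(start = 1, end = unname(annotation$chrom_lengths))
  )
  out[["Distal_Intergenic"]] <- GenomicRanges::setdiff(genome, taken, ignore.strand = TRUE)
  out
}

.sample_positions <- function(gr, n) {
  w <- GenomicRanges::width(gr)
  total <- sum(w)
  if (total < 1) abort("category has no available positions in this annotation")
  off <- sample.int(total, n, replace = TRUE) - 1L
  cum <- cumsum(w)
  piece <- findInterval(off, c(0, cum), rightmost.closed = FALSE)
  within <- off - c(0, cum)[piece]
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr))[piece],
    pos = GenomicRanges::start(gr)[piece] - 1L + within # 0-based
  )
}

#' Generate reads planted in known categories and TSS bins
#'
#' Places read anchors so that the localization precedence rules assign
#' exactly the planned category to each read (`loc_plan`), and/or at
#' offsets from a TSS falling in the planned bin (`tss_plan`). The
#' planting plan is the ground truth for recovery tests: with no
#' subsampling, computed LOC/TSS percentages equal the planned fractions
#' exactly.
#'
#' @param annotation a [genome_annotation()]; gene spacing must exceed
#'   twice the TSS window for `tss_plan` placement to be unambiguous
#' @param loc_plan named counts per localization category (names as in
#'   `feature_names("LOC")` without the prefix)
#' @param tss_plan named counts per TSS bin (names as in
#'   `feature_names("TSS")`, e.g. `"TSS_+2500"`)
#' @param promoter_bp,downstream_bp category geometry, as in
#'   [compute_loc_features()]
#' @param seed integer seed
#' @return A `read_set`.
#' @export
#' @examples
#' ann <- generate_toy_genome(seed = 1)
#' reads <- generate_reads_with_plan(ann, loc_plan = c(Promoter = 3, Distal_Intergenic = 7))
#' compute_loc_features(reads, ann)[["LOC_Promoter"]] # 30
generate_reads_with_plan <- function(annotation, loc_plan = NULL, tss_plan = NULL,
                                     promoter_bp = 3000, downstream_bp = 3000,
                                     seed = 1L) {
  if (is.null(loc_plan) && is.null(tss_plan)) abort("provide loc_plan and/or tss_plan")
  bins <- tss_bin_spec()
  tss <- annotation_tss(annotation)
  with_local_seed(seed, {
    parts <- list()
    if (!is.null(loc_plan)) {
      bad <- setdiff(names(loc_plan), .loc_categories)
      if (length(bad) > 0) {
        abort(paste0("unknown localization category: ", paste(bad, collapse = ", ")))
      }
      excl <- .exclusive_category_ranges(annotation, promoter_bp, downstream_bp)
      # keep LOC plants out of the TSS window so tss_plan bins stay exact
      if (!is.null(tss_plan)) {
        window <- GenomicRanges::GRanges(
          seqnames = tss$chrom,
          ranges = IRanges::IRanges(start = pmax(1, tss$pos + 1 - 5000), end = tss$pos + 1 + 5000)
        )
        excl <- purrr::map(excl, GenomicRanges::setdiff, GenomicRanges::reduce(window),
          ignore.strand = TRUE
        )
      }
      parts$loc <- purrr::map_dfr(names(loc_plan), function(cat) {
        n <- loc_plan[[cat]]
        if (n == 0) {
          return(tibble(chrom = character(0), pos = integer(0)))
        }
        if (sum(GenomicRanges::width(excl[[cat]])) < 1) {
          abort(paste0("plan unrealizable: no exclusive territory for ", cat))
        }
        .sample_positions(excl[[cat]], n)
      }) %>% mutate(strand = "+")
    }
    if (!is.null(tss_plan)) {
      bad <- setdiff(names(tss_plan), bins$feature)
      if (length(bad) > 0) {
        abort(paste0("unknown TSS bin: ", paste(bad, collapse = ", ")))
      }
      parts$tss <- purrr::map_dfr(names(tss_plan), function(bn) {
        n <- tss_plan[[bn]]
        if (n == 0) {
          return(tibble(chrom = character(0), pos = integer(0), strand = character(0)))
        }
        b <- bins[bins$feature == bn, ]
        which_tss <- rep_len(seq_len(nrow(tss)), n)
        off <- sample(seq(b$lower, b$upper - 1L), n, replace = TRUE)
        pos <- ifelse(tss$strand[which_tss] == "+",
          tss$pos[which_tss] + off,
          tss$pos[which_tss] - off
        )
        tibble(chrom = tss$chrom[which_tss], pos = as.integer(pos), strand = "+")
      })
    }
    df <- bind_rows(parts)
    if (any(df$pos < 0) ||
      any(df$pos >= annotation$chrom_lengths[df$chrom])) {
      abort("plan unrealizable: planted positions fall off the chromosome")
    }
    new_read_set(df, provenance = "full")
  })
}
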