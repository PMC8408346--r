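# Feature extraction: turn parsed QC inputs into the 47-feature vector.

# run code with a private RNG stream, leaving the global stream untouched
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Ordinal encoding of FastQC summary flags
#'
#' Encodes the 12 PASS/WARN/FAIL module flags as ordinal values preserving
#' the quality direction: `pass` = 2, `warning` = 1, `fail` = 0, so larger
#' means better for rank tests and auROC alike.
#'
#' @param flags named character vector from [parse_fastqc_summary()]
#' @return Named numeric vector over the 12 `RAW_*` features.
#' @export
encode_raw_features <- function(flags) {
  missing <- setdiff(feature_names("RAW"), names(flags))
  if (length(missing) > 0) {
    abort(paste0("incomplete flag set, missing: ", paste(missing, collapse = ", ")))
  }
  code <- c(pass = 2, warning = 1, fail = 0)
  bad <- setdiff(unique(unlist(flags)), names(code))
  if (length(bad) > 0) abort(paste0("unknown flag value(s): ", paste(bad, collapse = ", ")))
  vapply(feature_names("RAW"), function(f) code[[flags[[f]]]], numeric(1))
}

#' Mapping-rate features from aligner statistics
#'
#' Expands a mapping-statistics row into the 16 MAP feature slots. The
#' run-type-specific block (`MAP_SE_*` or `MAP_PE_*`) is filled and the
#' other left `NA`; the run-type-agnostic `MAP_MI_*` block equals the SE
#' features for single-end data and the concordant-pair features (plus the
#' overall alignment rate) for paired-end data, and is never `NA`.
#'
#' @param stats one-row tibble from [parse_aligner_log()]
#' @return Named numeric vector over the 16 `MAP_*` features.
#' @export
compute_map_features <- function(stats) {
  validate_mapping_stats(stats)
  out <- setNames(rep(NA_real_, 16), feature_names("MAP"))
  if (stats$run_type == "SE") {
    for (f in .map_se_fields) {
      out[[paste0("MAP_SE_", f)]] <- stats[[f]]
      out[[paste0("MAP_MI_", f)]] <- stats[[f]]
    }
  } else {
    for (f in .map_pe_fields) out[[paste0("MAP_PE_", f)]] <- stats[[f]]
    out[["MAP_MI_no_mapping"]] <- stats$con_no_mapping
    out[["MAP_MI_uniquely"]] <- stats$con_uniquely
    out[["MAP_MI_multiple"]] <- stats$con_multiple
    out[["MAP_MI_overall"]] <- stats$overall
  }
  out
}

#' Uniform subsample of a read set
#'
#' Draws `n` anchors uniformly without replacement. Read sets at or below
#' `n` are returned unchanged with provenance `"full"`; larger sets are
#' sampled deterministically for a given seed and marked `"subsampled"`.
#'
#' @param reads a `read_set`
#' @param n target sample size (default one million, the working size for
#'   localization and TSS features)
#' @param seed integer seed for the private sampling stream
#' @return A `read_set`.
#' @export
subsample_reads <- function(reads, n = 1e6, seed = 1L) {
  if (nrow(reads) == 0) abort("cannot subsample an empty read set")
  if (n < 1) abort("n must be >= 1")
  if (nrow(reads) <= n) {
    return(reads)
  }
  idx <- with_local_seed(seed, sample.int(nrow(reads), n))
  new_read_set(reads[sort(idx), ],
    provenance = "subsampled",
    file_id = attr(reads, "file_id"),
    n_skipped = attr(reads, "n_skipped")
  )
}

# anchors as width-1 GRanges (1-based)
.anchor_granges <- function(reads) {
  GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = reads$pos + 1L, width = 1L),
    strand = reads$strand
  )
}

# exons annotated with transcript-orientation rank and intron gaps
.tx_structure <- function(annotation) {
  tx <- annotation$transcripts
  ex <- left_join(annotation$exons,
    tx[, c("tx_id", "chrom", "strand")],
    by = "tx_id"
  ) %>%
    group_by(.data$tx_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(
      rank = if_else(.data$strand == "+",
        row_number(), dplyr::n() - row_number() + 1L
      )
    ) %>%
    ungroup()
  introns <- ex %>%
    group_by(.data$tx_id, .data$chrom, .data$strand) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    summarise(
      i_start = list(utils::head(.data$end, -1) + 1L),
      i_end = list(.data$start[-1] - 1L),
      .groups = "drop"
    ) %>%
    tidyr::unnest(c("i_start", "i_end")) %>%
    filter(.data$i_start <= .data$i_end) %>%
    rename(start = "i_start", end = "i_end") %>%
    group_by(.data$tx_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(
      rank = if_else(.data$strand == "+",
        row_number(), dplyr::n() - row_number() + 1L
      )
    ) %>%
    ungroup()
  list(exons = ex, introns = introns)
}

.gr_from_df <- function(df, chrom_lengths) {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(
      start = pmax(1L, as.integer(df$start)),
      end = pmin(as.integer(unname(chrom_lengths[df$chrom])), as.integer(df$end))
    )
  )
}

# Category interval sets in precedence order. Overlaps between categories
# are resolved at assignment time by precedence, so the sets themselves may
# overlap freely.
loc_category_ranges <- function(annotation, promoter_bp = 3000, downstream_bp = 3000) {
  tx <- annotation$transcripts
  cl <- annotation$chrom_lengths
  st <- .tx_structure(annotation)
  tss1 <- ifelse(tx$strand == "+", tx$start, tx$end) # 1-based TSS
  promoter <- tibble(chrom = tx$chrom, start = tss1 - promoter_bp, end = tss1 + promoter_bp)
  # UTRs: exonic sequence outside the CDS extent, 5' or 3' in transcript orientation
  utr5 <- utr3 <- tibble(chrom = character(), start = integer(), end = integer())
  if (nrow(annotation$cds) > 0) {
    cds_ext <- annotation$cds %>%
      group_by(.data$tx_id) %>%
      summarise(cds_start = min(.data$start), cds_end = max(.data$end), .groups = "drop")
    exc <- left_join(st$exons, cds_ext, by = "tx_id") %>% filter(!is.na(.data$cds_start))
    five <- exc %>%
      mutate(
        lo = if_else(.data$strand == "+", .data$start, pmax(.data$start, .data$cds_end + 1L)),
        hi = if_else(.data$strand == "+", pmin(.data$end, .data$cds_start - 1L), .data$end)
      ) %>%
      filter(.data$lo <= .data$hi)
    utr5 <- tibble(chrom = five$chrom, start = five$lo, end = five$hi)
    three <- exc %>%
      mutate(
        lo = if_else(.data$strand == "+", pmax(.data$start, .data$cds_end + 1L), .data$start),
        hi = if_else(.data$strand == "+", .data$end, pmin(.data$end, .data$cds_start - 1L))
      ) %>%
      filter(.data$lo <= .data$hi)
    utr3 <- tibble(chrom = three$chrom, start = three$lo, end = three$hi)
  }
  first_exon <- st$exons %>% filter(.data$rank == 1L)
  other_exon <- st$exons %>% filter(.data$rank > 1L)
  first_intron <- st$introns %>% filter(.data$rank == 1L)
  other_intron <- st$introns %>% filter(.data$rank > 1L)
  tx_end3 <- ifelse(tx$strand == "+", tx$end, tx$start) # transcript 3' end
  downstream <- tibble(
    chrom = tx$chrom,
    start = ifelse(tx$strand == "+", tx_end3 + 1L, tx_end3 - downstream_bp),
    end = ifelse(tx$strand == "+", tx_end3 + downstream_bp, tx_end3 - 1L)
  ) %>% filter(.data$start <= .data$end)
  list(
    Promoter = .gr_from_df(promoter, cl),
    `5_UTR` = .gr_from_df(utr5, cl),
    `3_UTR` = .gr_from_df(utr3, cl),
    `1st_Exon` = .gr_from_df(first_exon, cl),
    Other_Exon = .gr_from_df(other_exon, cl),
    `1st_Intron` = .gr_from_df(first_intron, cl),
    Other_Intron = .gr_from_df(other_intron, cl),
    Downstream = .gr_from_df(downstream, cl)
  )
}

#' Assign anchors to genomic-localization categories
#'
#' Every anchor is assigned to exactly one of the nine categories by the
#' precedence order Promoter > 5' UTR > 3' UTR > first exon > other exon >
#' first intron > other intron > downstream > distal intergenic. First/other
#' exons and introns are ranked in transcript orientation; the promoter
#' window and the downstream flank sizes are configurable.
#'
#' @param reads a `read_set`
#' @param annotation a `genome_annotation`
#' @param promoter_bp half-width of the promoter window around the TSS
#'   (default 3000)
#' @param downstream_bp flank past the transcript 3' end (default 3000)
#' @return Factor of category labels, one per anchor.
#' @export
assign_loc_category <- function(reads, annotation, promoter_bp = 3000,
                                downstream_bp = 3000) {
  if (nrow(annotation$transcripts) == 0) abort("empty annotation")
  cats <- loc_category_ranges(annotation, promoter_bp, downstream_bp)
  anchors <- .anchor_granges(reads)
  assigned <- rep(NA_character_, length(anchors))
  for (nm in names(cats)) {
    todo <- which(is.na(assigned))
    if (length(todo) == 0) break
    hits <- GenomicRanges::findOverlaps(anchors[todo], cats[[nm]],
      ignore.strand = TRUE
    )
    assigned[todo[unique(S4Vectors::queryHits(hits))]] <- nm
  }
  assigned[is.na(assigned)] <- "Distal_Intergenic"
  factor(assigned, levels = .loc_categories)
}

#' Genomic-localization features
#'
#' Percentage of anchors per genomic category; a partition, so the nine
#' values sum to 100.
#'
#' @inheritParams assign_loc_category
#' @return Named numeric vector over the 9 `LOC_*` features.
#' @export
compute_loc_features <- function(reads, annotation, promoter_bp = 3000,
                                 downstream_bp = 3000) {
  if (nrow(reads) == 0) abort("empty read set")
  cat <- assign_loc_category(reads, annotation, promoter_bp, downstream_bp)
  counts <- table(cat)
  setNames(
    100 * as.numeric(counts) / nrow(reads),
    paste0("LOC_", names(counts))
  )
}

#' Signed strand-oriented offsets to the nearest TSS
#'
#' For each anchor, the nearest TSS (by genomic distance; ties to the
#' lower-coordinate TSS) is found and the offset is signed in that TSS's
#' transcription direction: positive downstream of the TSS, negative
#' upstream. Anchors on chromosomes without a TSS get `NA`.
#'
#' @inheritParams assign_loc_category
#' @return Numeric vector of offsets (bp), one per anchor.
#' @export
tss_offsets <- function(reads, annotation) {
  tss <- annotation_tss(annotation)
  if (nrow(tss) == 0) abort("annotation contains no TSS")
  out <- rep(NA_real_, nrow(reads))
  for (ch in unique(reads$chrom)) {
    t <- tss %>%
      filter(.data$chrom == ch) %>%
      arrange(.data$pos)
    ri <- which(reads$chrom == ch)
    if (nrow(t) == 0) next
    pos <- reads$pos[ri]
    i <- findInterval(pos, t$pos)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, nrow(t))
    d_lo <- abs(pos - t$pos[lo])
    d_hi <- abs(pos - t$pos[hi])
    use_lo <- i >= 1 & (i >= nrow(t) | d_lo <= d_hi)
    nearest <- ifelse(use_lo, lo, hi)
    tpos <- t$pos[nearest]
    tstrand <- t$strand[nearest]
    out[ri] <- ifelse(tstrand == "+", pos - tpos, tpos - pos)
  }
  out
}

#' TSS-relative bin features
#'
#' Percentage of anchors whose strand-oriented offset to the nearest TSS
#' falls in each of the ten 1-kb bins spanning -5 kb to +5 kb. Anchors
#' outside the window contribute to no bin, so the ten values sum to at
#' most 100 (the denominator is the full read set).
#'
#' @inheritParams assign_loc_category
#' @param bins a bin table from [tss_bin_spec()]
#' @return Named numeric vector over the 10 `TSS_*` features.
#' @export
compute_tss_features <- function(reads, annotation, bins = tss_bin_spec()) {
  if (nrow(reads) == 0) abort("empty read set")
  off <- tss_offsets(reads, annotation)
  counts <- vapply(
    seq_len(nrow(bins)),
    function(i) sum(!is.na(off) & off >= bins$lower[[i]] & off < bins$upper[[i]]),
    numeric(1)
  )
  setNames(100 * counts / nrow(reads), bins$feature)
}

#' Assemble a 47-feature vector
#'
#' Combines the four feature blocks for one file into a single row. For
#' paired-end files the RAW block must come from the first mate (the
#' second mate's raw flags are redundant and dropped upstream); the
#' inapplicable MAP block is `NA`.
#'
#' @param file_id file identifier
#' @param run_type `"SE"` or `"PE"`
#' @param raw named vector from [encode_raw_features()]
#' @param map named vector from [compute_map_features()]
#' @param loc named vector from [compute_loc_features()]
#' @param tss named vector from [compute_tss_features()]
#' @return One-row tibble: `file_id`, `run_type`, then the 47 features.
#' @export
assemble_feature_vector <- function(file_id, run_type, raw, map, loc, tss) {
  blocks <- list(RAW = raw, MAP = map, LOC = loc, TSS = tss)
  for (b in names(blocks)) {
    if (is.null(blocks[[b]]) || length(blocks[[b]]) == 0) {
      abort(paste0("missing feature block: ", b))
    }
    missing <- setdiff(feature_names(b), names(blocks[[b]]))
    if (length(missing) > 0) {
      abort(paste0("block ", b, " missing: ", paste(missing, collapse = ", ")))
    }
  }
  expect_na <- if (run_type == "SE") "MAP_PE_" else "MAP_SE_"
  bad <- names(map)[startsWith(names(map), expect_na) & !is.na(map)]
  if (length(bad) > 0) {
    abort(paste0("run_type ", run_type, " but non-NA values in ", expect_na, "* block"))
  }
  vals <- c(raw, map, loc, tss)[feature_names()]
  bind_cols(
    tibble(file_id = file_id, run_type = run_type),
    as_tibble(as.list(vals))
  )
}

#' Write / read a feature table
#'
#' The feature table holds one row per file: `file_id`, metadata columns
#' prefixed `meta_`, and the 47 feature columns under their canonical
#' names. Values round-trip to six decimals.
#'
#' @param features tibble of feature rows
#' @param path CSV path
#' @return `path` (writer) or the tibble (reader).
#' @export
write_feature_table <- function(features, path) {
  readr::write_csv(features, path, na = "NA")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE, na = "NA")
  names(tab) <- ifelse(names(tab) %in% names(.feature_aliases),
    canonical_feature_name(names(tab)), names(tab)
  )
  # all-NA feature columns must stay numeric
  tab <- mutate(tab, across(any_of(feature_names()), as.numeric))
  as_tibble(tab)
}
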