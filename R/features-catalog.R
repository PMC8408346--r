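# The feature catalogue: 47 quality features in four sets.
#
# RAW  - FastQC summary flags, one ordinal feature per report module (12).
# MAP  - Bowtie2 mapping-rate percentages; SE and PE variants plus the
#        run-type-agnostic MI ("mixed") block shared by both run types.
# LOC  - percentage of mapped reads per genomic category (9).
# TSS  - percentage of mapped reads per 1-kb bin within +/-5 kb of the
#        nearest transcription start site (10).

.raw_modules <- c(
  "Basic_Statistics",
  "Per_base_sequence_quality",
  "Per_tile_sequence_quality",
  "Per_sequence_quality_scores",
  "Per_base_sequence_content",
  "Per_sequence_GC_content",
  "Per_base_N_content",
  "Sequence_Length_Distribution",
  "Sequence_Duplication_Levels",
  "Overrepresented_sequences",
  "Adapter_Content",
  "Kmer_Content"
)

.loc_categories <- c(
  "Promoter", "5_UTR", "3_UTR", "1st_Exon", "Other_Exon",
  "1st_Intron", "Other_Intron", "Downstream", "Distal_Intergenic"
)

.map_se_fields <- c("no_mapping", "uniquely", "multiple", "overall")
.map_pe_fields <- c(
  "con_no_mapping", "con_uniquely", "con_multiple", "dis_uniquely",
  "cod_no_mapping", "cod_uniquely", "cod_multiple", "overall"
)

#' TSS bin specification
#'
#' Ten half-open 1-kb bins partitioning the window from -5,000 to +5,000 bp
#' around a transcription start site, labelled by their centres. An offset
#' `o` (in transcript orientation: positive downstream of the TSS) falls in
#' the bin whose centre is `c` when `o` is in `[c - 500, c + 500)`.
#'
#' @param window_bp half-window size in bp (default 5000)
#' @param bin_bp bin width in bp (default 1000)
#' @return A tibble with columns `center`, `lower`, `upper` (half-open
#'   `[lower, upper)`) and `feature` (the feature-column name).
#' @export
#' @examples
#' tss_bin_spec()
tss_bin_spec <- function(window_bp = 5000, bin_bp = 1000) {
  stopifnot(window_bp %% bin_bp == 0)
  lower <- seq(-window_bp, window_bp - bin_bp, by = bin_bp)
  center <- lower + bin_bp / 2
  tibble(
    center = center,
    lower = lower,
    upper = lower + bin_bp,
    feature = paste0("TSS_", ifelse(center > 0, "+", ""), center)
  )
}

#' Names of the 47 quality features
#'
#' Returns the canonical feature names, optionally restricted to one feature
#' set. The four sets are `RAW` (12 FastQC summary flags, ordinal-encoded),
#' `MAP` (4 single-end + 4 run-type-agnostic + 8 paired-end mapping-rate
#' percentages), `LOC` (9 genomic-localization percentages) and `TSS`
#' (10 TSS-relative bin percentages).
#'
#' @param set one of `"all"`, `"RAW"`, `"MAP"`, `"LOC"`, `"TSS"`
#' @return character vector of feature names (47 for `"all"`).
#' @export
#' @examples
#' length(feature_names())          # 47
#' feature_names("LOC")
feature_names <- function(set = c("all", "RAW", "MAP", "LOC", "TSS")) {
  set <- match.arg(set)
  raw <- paste0("RAW_", .raw_modules)
  map <- c(
    paste0("MAP_SE_", .map_se_fields),
    paste0("MAP_MI_", .map_se_fields),
    paste0("MAP_PE_", .map_pe_fields)
  )
  loc <- paste0("LOC_", .loc_categories)
  tss <- tss_bin_spec()$feature
  switch(set,
    all = c(raw, map[1:8], loc, tss, map[9:16]),
    RAW = raw,
    MAP = map,
    LOC = loc,
    TSS = tss
  )
}

# Supplementary-style long aliases (e.g. MAP_MI_overall_mapping) are accepted
# on input and canonicalized to the short names above.
.feature_aliases <- local({
  short <- c(
    paste0("MAP_SE_", .map_se_fields),
    paste0("MAP_MI_", .map_se_fields),
    paste0("MAP_PE_", .map_pe_fields)
  )
  long <- paste0(short, "_mapping")
  setNames(short, long)
})

#' Canonicalize feature names
#'
#' Maps long-form aliases (`MAP_MI_overall_mapping`) to the canonical
#' short names (`MAP_MI_overall`); canonical names pass through unchanged.
#'
#' @param x character vector of feature names
#' @return character vector of canonical names
#' @export
canonical_feature_name <- function(x) {
  hit <- x %in% names(.feature_aliases)
  x[hit] <- .feature_aliases[x[hit]]
  x
}
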