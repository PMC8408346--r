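# Feature extraction: the 47-feature vector.

test_that("the catalogue lists exactly the 47 canonical features", {
  expect_length(feature_names(), 47)
  expect_length(feature_names("RAW"), 12)
  expect_length(feature_names("MAP"), 16)
  expect_length(feature_names("LOC"), 9)
  expect_length(feature_names("TSS"), 10)
  expect_equal(anyDuplicated(feature_names()), 0)
  expect_true(all(c("TSS_-4500", "TSS_+4500", "LOC_5_UTR", "MAP_PE_cod_multiple")
  %in% feature_names()))
})

test_that("flag encoding is the monotone pass>warning>fail map", {
  all_pass <- setNames(rep("pass", 12), feature_names("RAW"))
  expect_true(all(encode_raw_features(all_pass) == 2))
  mixed <- all_pass
  mixed[["RAW_Adapter_Content"]] <- "fail"
  mixed[["RAW_Kmer_Content"]] <- "warning"
  enc <- encode_raw_features(mixed)
  expect_equal(enc[["RAW_Adapter_Content"]], 0)
  expect_equal(enc[["RAW_Kmer_Content"]], 1)
  expect_true(enc[["RAW_Basic_Statistics"]] > enc[["RAW_Kmer_Content"]])
})

test_that("MAP features mirror SE stats into the run-type-agnostic block", {
  st <- parse_aligner_log(bowtie2_se_log(10, 70, 20), "SE")
  m <- compute_map_features(st)
  expect_equal(unname(m[paste0("MAP_MI_", c("no_mapping", "uniquely", "multiple", "overall"))]),
    c(10, 70, 20, 90))
  expect_equal(unname(m[paste0("MAP_SE_", c("no_mapping", "uniquely", "multiple", "overall"))]),
    c(10, 70, 20, 90))
  expect_true(all(is.na(m[startsWith(names(m), "MAP_PE_")])))
  expect_equal(m[["MAP_MI_overall"]], 100 - m[["MAP_MI_no_mapping"]])
})

test_that("PE MAP_MI comes from the concordant categories plus overall", {
  st <- parse_aligner_log(bowtie2_pe_log(con_uniq = 55, con_no = 25, con_multi = 20), "PE")
  m <- compute_map_features(st)
  expect_equal(m[["MAP_MI_uniquely"]], 55)
  expect_equal(m[["MAP_MI_no_mapping"]], 25)
  expect_equal(m[["MAP_MI_overall"]], 95.5)
  expect_true(all(is.na(m[startsWith(names(m), "MAP_SE_")])))
  expect_equal(m[["MAP_PE_con_uniquely"]], 55)
})

test_that("subsampling is a seeded no-replacement draw with a no-op branch", {
  ann <- generate_toy_genome(seed = 9)
  rs <- generate_reads_with_plan(ann, loc_plan = c(Distal_Intergenic = 500))
  expect_identical(subsample_reads(rs, n = 1e6), rs) # below target: unchanged
  s1 <- subsample_reads(rs, n = 100, seed = 7)
  s2 <- subsample_reads(rs, n = 100, seed = 7)
  expect_equal(nrow(s1), 100)
  expect_identical(s1$pos, s2$pos)
  expect_equal(attr(s1, "provenance"), "subsampled")
  expect_equal(anyDuplicated(paste(s1$chrom, s1$pos, seq_len(100))), 0)
  expect_error(subsample_reads(rs[0, ], 10), "empty")
})

test_that("planted localization plans are recovered exactly", {
  ann <- generate_toy_genome(seed = 1)
  rd <- generate_reads_with_plan(ann,
    loc_plan = c(Promoter = 3, `1st_Exon` = 2, Distal_Intergenic = 5), seed = 2
  )
  loc <- compute_loc_features(rd, ann)
  expect_equal(unname(loc), c(30, 0, 0, 20, 0, 0, 0, 0, 50))
  plan <- setNames(
    c(10, 5, 5, 10, 10, 10, 10, 10, 30),
    c("Promoter", "5_UTR", "3_UTR", "1st_Exon", "Other_Exon",
      "1st_Intron", "Other_Intron", "Downstream", "Distal_Intergenic")
  )
  loc2 <- compute_loc_features(generate_reads_with_plan(ann, loc_plan = plan, seed = 3), ann)
  expect_equal(unname(loc2), unname(plan))
  expect_equal(sum(loc2), 100)
})

test_that("the localization partition always sums to 100", {
  ann <- generate_toy_genome(seed = 5)
  set.seed(5)
  # arbitrary positions across the chromosome, not planted
  rnd <- seqguide:::new_read_set(tibble::tibble(
    chrom = "chrT", pos = sample.int(2.4e5, 400), strand = sample(c("+", "-"), 400, TRUE)
  ))
  expect_equal(sum(compute_loc_features(rnd, ann)), 100, tolerance = 1e-9)
})

test_that("TSS offsets are strand-oriented and binned half-open", {
  ann <- genome_annotation(
    c(chrA = 50000, chrB = 50000),
    tibble::tibble(
      tx_id = c("t1", "t2"), gene_id = c("g1", "g2"),
      chrom = c("chrA", "chrB"), start = c(10001, 5001), end = c(15000, 10001),
      strand = c("+", "-")
    ),
    tibble::tibble(tx_id = c("t1", "t2"), start = c(10001, 5001), end = c(15000, 10001))
  )
  # + strand TSS at 0-based 10000: anchor 12400 -> offset +2400 -> TSS_+2500
  # - strand TSS at 0-based 10000: anchor 7600  -> offset +2400 -> TSS_+2500
  rs <- seqguide:::new_read_set(tibble::tibble(
    chrom = c("chrA", "chrB"), pos = c(12400L, 7600L), strand = "+"
  ))
  expect_equal(tss_offsets(rs, ann), c(2400, 2400))
  tssf <- compute_tss_features(rs, ann)
  expect_equal(tssf[["TSS_+2500"]], 100)
  expect_equal(sum(tssf), 100)
  # outside the window: no bin counts it
  far <- seqguide:::new_read_set(tibble::tibble(chrom = "chrA", pos = 16000L, strand = "+"))
  expect_equal(sum(compute_tss_features(far, ann)), 0)
  # exactly +5000 is outside the half-open window, -5000 inside
  edge <- seqguide:::new_read_set(tibble::tibble(
    chrom = "chrA", pos = c(15000L, 5000L), strand = "+"
  ))
  tf <- compute_tss_features(edge, ann)
  expect_equal(tf[["TSS_-4500"]], 50)
  expect_equal(sum(tf), 50)
})

test_that("planted TSS plans are recovered exactly, minus strand mirrored", {
  ann <- generate_toy_genome(seed = 1)
  rd <- generate_reads_with_plan(ann, tss_plan = c(`TSS_+2500` = 40, `TSS_-500` = 60), seed = 8)
  tf <- compute_tss_features(rd, ann)
  expect_equal(tf[["TSS_+2500"]], 40)
  expect_equal(tf[["TSS_-500"]], 60)
  expect_equal(sum(tf), 100)
})

test_that("minus-strand gene plans reproduce the mirrored plus-strand output", {
  mk <- function(strand) {
    L <- 200000L
    s <- if (strand == "+") 50001L else L - 50000L - 35999L
    genome_annotation(
      c(chrM = L),
      tibble::tibble(
        tx_id = "t1", gene_id = "g1", chrom = "chrM",
        start = 50001L, end = 86000L, strand = strand
      ),
      tibble::tibble(
        tx_id = "t1",
        start = 50001L + c(0L, 14400L, 28800L),
        end = 50001L + c(7199L, 21599L, 35999L)
      ),
      tibble::tibble(
        tx_id = "t1",
        start = 50001L + c(3600L, 14400L, 28800L),
        end = 50001L + c(7199L, 21599L, 32399L)
      )
    )
  }
  plan <- c(Promoter = 10, `5_UTR` = 10, `1st_Exon` = 20, `1st_Intron` = 20,
    Downstream = 10, Distal_Intergenic = 30)
  loc_plus <- compute_loc_features(
    generate_reads_with_plan(mk("+"), loc_plan = plan, seed = 4), mk("+")
  )
  loc_minus <- compute_loc_features(
    generate_reads_with_plan(mk("-"), loc_plan = plan, seed = 4), mk("-")
  )
  expect_equal(loc_plus, loc_minus)
  expect_equal(unname(loc_plus[paste0("LOC_", names(plan))]), unname(plan))
})

test_that("subsampled LOC fractions agree with the full set within 3 SE", {
  ann <- generate_toy_genome(seed = 3)
  rd <- generate_reads_with_plan(ann,
    loc_plan = c(Promoter = 3000, `1st_Intron` = 3000, Distal_Intergenic = 4000),
    seed = 6
  )
  full <- compute_loc_features(rd, ann)
  sub <- compute_loc_features(subsample_reads(rd, n = 2000, seed = 10), ann)
  for (f in names(full)) {
    p <- full[[f]] / 100
    se <- sqrt(p * (1 - p) / 2000) * 100
    expect_lt(abs(sub[[f]] - full[[f]]), max(3 * se, 1e-9) + 1e-9)
  }
})

test_that("assembled vectors carry the run-type NA pattern", {
  raw <- encode_raw_features(setNames(rep("pass", 12), feature_names("RAW")))
  map_se <- compute_map_features(parse_aligner_log(bowtie2_se_log(), "SE"))
  ann <- generate_toy_genome(seed = 1)
  rd <- generate_reads_with_plan(ann, loc_plan = c(Promoter = 5, Distal_Intergenic = 5))
  loc <- compute_loc_features(rd, ann)
  tss <- compute_tss_features(rd, ann)
  fv <- assemble_feature_vector("f1", "SE", raw, map_se, loc, tss)
  expect_equal(names(fv), c("file_id", "run_type", feature_names()))
  expect_equal(sum(!is.na(fv[feature_names()])), 39) # 47 - 8 PE slots
  expect_true(all(is.na(fv[paste0("MAP_PE_", c("overall", "con_uniquely"))])))

  map_pe <- compute_map_features(parse_aligner_log(bowtie2_pe_log(), "PE"))
  fv_pe <- assemble_feature_vector("f2", "PE", raw, map_pe, loc, tss)
  expect_true(all(is.na(fv_pe[paste0("MAP_SE_", c("no_mapping", "overall"))])))
  expect_false(anyNA(fv_pe[paste0("MAP_MI_", c("no_mapping", "uniquely", "multiple", "overall"))]))
  expect_error(assemble_feature_vector("f3", "SE", raw, map_pe, loc, tss), "MAP_PE")
  expect_error(assemble_feature_vector("f3", "SE", raw[-1], map_se, loc, tss), "RAW")
})
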