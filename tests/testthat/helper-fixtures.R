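# Fixture builders and independent oracles shared across the suite.

fastqc_display_names <- function() {
  gsub("_", " ", sub("^RAW_", "", feature_names("RAW")))
}

fastqc_lines <- function(statuses = rep("PASS", 12)) {
  paste(statuses, fastqc_display_names(), "sample.fastq", sep = "\t")
}

# Bowtie2-style SE log with the given category percentages (must sum to 100)
bowtie2_se_log <- function(no = 10, uniq = 70, multi = 20, n = 10000) {
  fmt <- function(p) sprintf("%.2f", p)
  c(
    sprintf("%d reads; of these:", n),
    sprintf("  %d (100.00%%) were unpaired; of these:", n),
    sprintf("    %d (%s%%) aligned 0 times", round(n * no / 100), fmt(no)),
    sprintf("    %d (%s%%) aligned exactly 1 time", round(n * uniq / 100), fmt(uniq)),
    sprintf("    %d (%s%%) aligned >1 times", round(n * multi / 100), fmt(multi)),
    sprintf("%s%% overall alignment rate", fmt(100 - no))
  )
}

bowtie2_pe_log <- function(con_no = 10, con_uniq = 70, con_multi = 20,
                           dis_uniq = 15, cod_no = 50, cod_uniq = 33.33,
                           cod_multi = 16.67, overall = 95.5, n = 10000) {
  fmt <- function(p) sprintf("%.2f", p)
  c(
    sprintf("%d reads; of these:", n),
    sprintf("  %d (100.00%%) were paired; of these:", n),
    sprintf("    %d (%s%%) aligned concordantly 0 times", round(n * con_no / 100), fmt(con_no)),
    sprintf("    %d (%s%%) aligned concordantly exactly 1 time", round(n * con_uniq / 100), fmt(con_uniq)),
    sprintf("    %d (%s%%) aligned concordantly >1 times", round(n * con_multi / 100), fmt(con_multi)),
    "    ----",
    sprintf("    %d pairs aligned concordantly 0 times; of these:", round(n * con_no / 100)),
    sprintf("      %d (%s%%) aligned discordantly 1 time", round(n * con_no / 100 * dis_uniq / 100), fmt(dis_uniq)),
    "    ----",
    "    850 pairs aligned 0 times concordantly or discordantly; of these:",
    "      1700 mates make up the pairs; of these:",
    sprintf("        850 (%s%%) aligned 0 times", fmt(cod_no)),
    sprintf("        567 (%s%%) aligned exactly 1 time", fmt(cod_uniq)),
    sprintf("        283 (%s%%) aligned >1 times", fmt(cod_multi)),
    sprintf("%s%% overall alignment rate", fmt(overall))
  )
}

# minimal single-end SAM file: n_plus/+ strand, n_minus/- strand, n_unmapped
write_sam_fixture <- function(path, n_plus = 4, n_minus = 3, n_unmapped = 3,
                              chrom = "chrT", chrom_len = 10000) {
  recs <- c(
    sprintf("@HD\tVN:1.6\tSO:unsorted"),
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len)
  )
  i <- 0
  for (k in seq_len(n_plus)) {
    i <- i + 1
    recs <- c(recs, sprintf(
      "r%02d\t0\t%s\t%d\t60\t4M\t*\t0\t0\tACGT\tIIII", i, chrom, 100 + 10 * k
    ))
  }
  for (k in seq_len(n_minus)) {
    i <- i + 1
    recs <- c(recs, sprintf(
      "r%02d\t16\t%s\t%d\t60\t4M\t*\t0\t0\tACGT\tIIII", i, chrom, 500 + 10 * k
    ))
  }
  for (k in seq_len(n_unmapped)) {
    i <- i + 1
    recs <- c(recs, sprintf("r%02d\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\tIIII", i))
  }
  writeLines(recs, path)
  path
}

# brute-force auROC: pairwise concordance with ties counted one half
auroc_pairs_oracle <- function(values, labels) {
  x <- values[labels == "high"]
  y <- values[labels == "low"]
  conc <- 0
  for (a in x) {
    for (b in y) {
      conc <- conc + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  a1 <- conc / (length(x) * length(y))
  max(a1, 1 - a1)
}

# ---- naive recursive CART oracle (independent of the package's search) ----

oracle_gini <- function(lab) {
  p <- mean(lab == "high")
  1 - p^2 - (1 - p)^2
}

# exhaustive double-loop split search; goodness compared as the exact
# integer fraction A/D (A = (pl^2+ql^2)*nr + (pr^2+qr^2)*nl, D = nl*nr),
# tie-break: feature order, then smallest threshold
oracle_best_split <- function(data, lab, features) {
  parent <- oracle_gini(lab)
  if (parent == 0) {
    return(NULL)
  }
  n <- length(lab)
  best <- NULL
  for (f in features) {
    v <- data[[f]]
    if (anyNA(v)) next
    sv <- sort(unique(v))
    if (length(sv) < 2) next
    for (t in (utils::head(sv, -1) + sv[-1]) / 2) {
      l <- lab[v <= t]
      r <- lab[v > t]
      pl <- sum(l == "high")
      ql <- sum(l == "low")
      pr <- sum(r == "high")
      qr <- sum(r == "low")
      a <- (pl^2 + ql^2) * length(r) + (pr^2 + qr^2) * length(l)
      d <- length(l) * length(r)
      dec <- parent - length(l) / n * oracle_gini(l) - length(r) / n * oracle_gini(r)
      if (is.null(best) || a * best$d > best$a * d) {
        best <- list(feature = f, threshold = t, decrease = dec, a = a, d = d)
      }
    }
  }
  best
}

oracle_total_decrease <- function(data, lab, features, max_depth, depth = 0) {
  if (depth >= max_depth || oracle_gini(lab) == 0) {
    return(0)
  }
  s <- oracle_best_split(data, lab, features)
  if (is.null(s)) {
    return(0)
  }
  go_left <- data[[s$feature]] <= s$threshold
  n <- length(lab)
  s$decrease +
    sum(go_left) / n *
      oracle_total_decrease(data[go_left, , drop = FALSE], lab[go_left], features, max_depth, depth + 1) +
    sum(!go_left) / n *
      oracle_total_decrease(data[!go_left, , drop = FALSE], lab[!go_left], features, max_depth, depth + 1)
}

# total weighted Gini decrease of a fitted qc_tree
tree_total_decrease <- function(tree) {
  nodes <- tidy(tree)
  leaves <- nodes[nodes$leaf, ]
  nodes$gini[nodes$node == 1] -
    sum(leaves$samples / nodes$samples[nodes$node == 1] * leaves$gini)
}

h3k4me1_guideline_tree <- function() {
  import_tree_json(system.file("extdata", "tree_h3k4me1_human_se.json",
    package = "seqguide"
  ))
}

# one-subset group-A blueprint
blueprint_one <- function(n_high = 15, n_low = 15, sample = "K562", run_type = "SE") {
  tibble::tibble(
    organism = "human", assay = "ChIP-seq", assay_title = "TF ChIP-seq",
    run_type = run_type, biological_sample = sample,
    n_high = n_high, n_low = n_low
  )
}
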