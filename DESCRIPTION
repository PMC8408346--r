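Package: seqguide
Title: Data-Driven Quality-Control Guidelines for NGS Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives condition-specific quality-control guidelines for
    functional-genomics sequencing files (ChIP-seq, RNA-seq, DNase-seq).
    Computes a 47-feature quality profile per file from FastQC summary
    flags, Bowtie2 mapping statistics, genomic localization of mapped
    reads and read density around transcription start sites; stratifies
    corpora into experimental-condition subsets; quantifies each
    feature's discriminative power (Wilcoxon-Mann-Whitney tests with
    Benjamini-Hochberg correction) and classification power
    (orientation-maximized auROC); induces interpretable depth-limited
    CART decision trees as per-condition guidelines; and audits
    fixed-threshold guideline schemes (ENCODE numeric minima, the
    Cistrome six-flag system). Includes a synthetic-data module that
    generates metadata corpora, quality-dependent feature tables, toy
    genomes with annotated read sets, and six-metric quality profiles
    with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
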