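---
title: "Deriving condition-specific NGS quality-control guidelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving condition-specific NGS quality-control guidelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqguide)
```

## The procedure

`seqguide` models quality control of functional-genomics sequencing files as
a supervised problem: each file carries a binary curation label (`high` /
`low`), a 47-feature quality profile, and metadata describing its
experimental condition. The pipeline asks, per condition, which features
*discriminate* the classes (rank tests), how well each feature *classifies*
on its own (auROC), and what small decision rule *combines* features into a
practical guideline (a depth-limited CART tree).

### The 47 features

* **RAW (12)** — FastQC summary flags per report module, ordinal-encoded
  pass = 2, warning = 1, fail = 0. The encoding is monotone so rank tests and
  auROC see the intended quality direction; its spacing is irrelevant to both
  (they are rank-based). The full 12-module set includes the basic-statistics
  module, which never fails in practice and therefore sits at auROC 0.5;
  reports may drop it but the vector carries it for completeness.
* **MAP (16)** — mapping-rate percentages parsed from a Bowtie2-style run
  log, as printed (two decimals, units: percent of reads/pairs). Single-end
  files fill `MAP_SE_*` (unmapped / uniquely / multiply mapped / overall),
  paired-end files the eight `MAP_PE_*` rates (concordant categories,
  discordant-unique, and the three rates for mates of unaligned pairs). The
  run-type-agnostic `MAP_MI_*` block equals the SE block for SE files and
  the concordant-pair categories for PE files; the overall alignment rate is
  run-type-agnostic, so `MAP_MI_overall` is the log's overall rate in both
  cases. The block not matching the run type is `NA`, and those `NA`s
  propagate (they never enter tests or the FDR pool).
* **LOC (9)** — percent of read anchors per genomic category. An anchor is
  the strand-aware 5′ end of a mapped read (0-based; start for `+`, end − 1
  for `-`); paired-end files contribute one anchor per properly oriented
  pair, at the leftmost mate's 5′ end, so SE and PE files are on the same
  per-fragment footing. Each anchor is assigned to exactly one category by
  precedence: Promoter > 5′ UTR > 3′ UTR > first exon > other exon > first
  intron > other intron > downstream > distal intergenic. The promoter
  window (TSS ± 3,000 bp) and the downstream flank (3,000 bp past the 3′
  end) are configurable, since annotation packages differ in these defaults.
  The categories partition the genome, so the nine values sum to 100.
* **TSS (10)** — percent of anchors whose offset to the *nearest* TSS falls
  in each of ten half-open 1-kb bins `[c − 500, c + 500)` on centres −4,500 …
  +4,500. Offsets are signed in the transcription direction of that TSS
  (positive downstream), which makes upstream/downstream meaningful on both
  strands; nearest-TSS ties break to the lower-coordinate TSS. Anchors
  beyond ±5 kb count toward no bin, so the bin sum is ≤ 100.

Percent denominators: LOC/TSS use the analysed read set (after the optional
uniform subsample of 10⁶ reads, the standard working size that keeps memory
flat; the subsample is seeded and skipped for smaller files); MAP rates are
taken from the aligner's own printed denominators. For paired-end files the
RAW block comes from the first mate only — the second mate's flags are
nearly redundant with the first's and would double-count that file's raw
quality.

### Stratification

Five subset groups stratify a corpus: organism × assay × run type (group 1),
organism × assay title × run type (group 2), and the three condition-level
groups adding biological sample (A), ChIP target (B), or target + antibody
(C). `assay` and `assay title` are distinct metadata columns (an assay title
such as "Histone ChIP-seq" refines the assay "ChIP-seq"). A record lacking a
defining field simply drops out of that group. Only subsets with at least
`k = 10` files (inclusive, configurable) are evaluated: below that, neither
the rank test nor a tree is meaningful.

### Feature power

For each (subset, feature) pair the high and low values are compared with a
two-sided Wilcoxon–Mann–Whitney test. Two branches:

* **exact** — for tie-free samples with n₁ + n₂ ≤ 12, the permutation null
  of U is enumerated (≤ 924 labelings) and p = P(|U − μ| ≥ |u − μ|);
* **normal** — otherwise, the normal approximation with tie correction and a
  0.5 continuity correction. Ordinal RAW features are tie-heavy by nature
  and always take this branch.

Two-sided throughout: the direction of a feature's effect is unknown a
priori and handled separately by the orientation-maximized auROC,
auROC\* = max(a, 1 − a) with a = U/(n₁n₂) and ties counted ½ concordant.
auROC\* is always in [0.5, 1] and invariant to sign flips of the feature.

Benjamini–Hochberg adjustment is applied once to the pooled p-values of all
(subset × feature) tests of one group — the multiplicity that matters when a
whole group is scanned for guidelines; per-subset pooling is available
behind a flag. Pairs where either class has fewer than two non-missing
values are reported as NA rows and excluded from the BH pool `m`, mirroring
the real-data situation where a condition has no testable signal at all.
Significance-count rankings use a strict `fdr < cutoff` at 0.01 / 0.001 /
0.0001; the per-feature auROC summary reports the arithmetic mean as the
headline (with the median alongside, which is more robust for the many
small subsets).

### Guideline trees

Per subset, a binary CART tree on the Gini criterion with maximum depth 3:
deep enough to express condition-specific interactions, shallow enough to
read as a guideline. Candidate thresholds sit at midpoints of consecutive
distinct sorted values; the left branch takes `value ≤ threshold`, matching
the "equal or less" reading of published guideline trees. There is no
pruning and no minimum leaf size beyond 1 — small leaves are the point of an
interpretable audit trail. A node splits whenever it is impure and any
usable feature is non-constant, *including* zero-decrease splits: an
XOR-like pattern has no impurity-reducing first split, yet the standard CART
greedy recursion (and this one) still separates it perfectly at depth 2.
Leaf prediction is the majority class; ties predict `low` — for quality
control, the conservative call is to flag the file for review. Features
containing missing values within a node are not split candidates (within a
condition subset every file shares a run type, so a feature is either fully
present or fully absent there), which keeps tree application total on
training data; applying a tree to a vector missing a tested feature is an
error naming that feature.

**Numerical determinism.** The split goodness is, up to node constants, the
fraction `A/D` with `A = (p_l² + q_l²)·n_r + (p_r² + q_r²)·n_l` and
`D = n_l·n_r` — all integers. Candidate splits are ranked by integer
cross-multiplication, so the chosen split never depends on floating-point
rounding; ties break to the earlier feature (canonical catalogue order),
then the smaller threshold. Trees are therefore invariant to row order and
reproducible across platforms. (Exact up to node sizes ≈ 1,500 files, far
beyond the condition subsets this is built for.) Thresholds are stored at
full precision and printed rounded to 3 decimals.

The tests verify the fitter against a naive exhaustive per-node split
search — the definitional CART recursion written as double loops — rather
than against a globally optimal depth-2 tree: greedy CART is not a global
optimizer (on random 12 × 3 instances it attains the globally best total
Gini decrease only ~60% of the time, a property shared by every standard
CART implementation), so per-node exhaustive equivalence is the meaningful
oracle.

### Guideline audits

Published numeric minima (per-assay minimum aligned / uniquely mapped reads
/ useable fragments) are audited with *inclusive* bounds — they are stated
as minimal acceptable values. The six-metric flag system is audited with
*strictly-above* thresholds (a metric exactly at its threshold flags bad),
matching the "greater than" wording of its definition; flagging is monotone
by construction. The FastQC-score threshold defaults to 25 in score units
(not the 0.25 fraction occasionally printed elsewhere); both scales can be
set via the `thresholds` argument. Implausible profiles (median quality
score > 100, mapping ratio > 1) are removed up front; the filter is
idempotent. The flag-consistency diagnostic groups each focal metric by the
number of *other* bad flags (0–5) and correlates metric against that count
(Pearson/Spearman/Kendall tau-b); an informative, consistent metric shows a
negative coefficient.

## The synthetic-data module

The generators exist so that every pipeline stage can be tested against
known ground truth; they emulate the *statistical shape* of a curated
corpus, not its content:

* **Corpora** — subset blueprints (metadata values + class sizes, default
  regime 10–40 files per subset, the small-sample regime where these methods
  live) with per-feature effect specs. Continuous features are latent
  normal with a class shift of `d` within-class SDs, so the orientation-max
  auROC has the closed form Φ(d/√2); the lognormal option exponentiates the
  same latent (rank statistics unchanged), and ordinal features discretize
  it at fixed cuts (≈ 10% fail / 20% warning / 70% pass under the null).
  The run-type NA pattern of real data is reproduced.
* **Toy genomes** — non-overlapping three-exon transcripts with CDS-derived
  UTRs, alternating strands, spaced so promoter windows, TSS windows and
  downstream flanks never collide; serializable to GFF3 and back.
* **Read plans** — anchors placed inside each category's
  *precedence-exclusive* territory (or at exact TSS offsets), so computed
  LOC/TSS percentages equal the planted fractions with no tolerance.
* **Six-metric profiles** — a latent per-file badness drives all metrics
  down monotonically with configurable noise (at zero noise, strictly), or
  metrics are drawn independently to probe the null of the flag-consistency
  diagnostics; implausible outliers can be planted.

What passing these tests shows: the statistical machinery, the geometry of
the LOC/TSS definitions, and the end-to-end plumbing are correct. What it
does not show: anything about real corpora — real features are not
normal-shifted, real metadata are biased toward a few cell types and
antibodies (the composition summaries exist precisely to surface that), and
real labels embed curator judgment. Published corpus-level numbers (per-
feature mean auROC tables, subset inventories, flag correlations) therefore
cannot be reproduced here and are not asserted anywhere.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| subsample size | 10⁶ | reads | standard working size for LOC/TSS; seeded, skipped below |
| promoter window | ±3,000 | bp around TSS | common annotation-package default; configurable |
| downstream flank | 3,000 | bp past 3′ end | same |
| TSS window / bin | ±5,000 / 1,000 | bp | ten bins labelled by centre, half-open |
| minimum subset size | 10 | files | inclusive; below this neither test nor tree is informative |
| FDR cutoffs | 0.01, 0.001, 10⁻⁴ | — | strict comparison, pooled per group |
| tree depth | 3 | splits | interpretability / expressiveness trade-off |
| exact-test bound | 12 | n₁ + n₂ | full enumeration is cheap and exact below it |
| flag thresholds | 25, 0.6, 0.8, 0.01, 0.7, 500 | mixed | strictly-above; all configurable |

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run at sizes chosen to give tight
Monte-Carlo error while staying desk-scale: analytic auROC recovery at
n = 2,000 + 2,000 over 20 seeds (MC error of the mean ≈ 0.002, against a
±0.01 band); end-to-end recovery over 100 corpora of 30 + 30 files with
d = 3 (the planted feature must be the unique `fdr < 0.01` hit and the tree
root in ≥ 95); false-discovery control over 100 null corpora (≈ 3,900
tests); oracle equivalence over 1,000 random instances for the rank/auROC
primitives and the tree fitter. Read-plan recovery uses toy genomes of five
36-kb genes on a 250-kb chromosome — small enough to enumerate, large
enough that every category keeps exclusive territory.

## Known limitations

* Training-set accuracy is the only tree performance reported, as in the
  guideline-publication setting it mirrors; there is no cross-validation,
  so tree accuracies are optimistic and the documentation says so.
* Trees are unstable to small training perturbations by nature; the
  evaluations table (sample sizes, FDR, auROC) is the stability context a
  user should read alongside any single tree.
* The LOC precedence and window sizes are conventions, not facts; changing
  them changes the LOC features. They are exposed as parameters and fixed
  defaults are documented.
* `mann_whitney`'s exact branch is limited to tie-free small samples;
  tie-heavy ordinal data always use the corrected approximation, which is
  standard but approximate at very small n.
* The audit module consumes precomputed metric tables; it never recomputes
  FRiP, library-complexity or peak statistics from raw reads.
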