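---
title: "Methods: sex-chromosome-complement-aware differential expression"
author: "placentaSexDE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-chromosome-complement-aware differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placentaSexDE)
```

# Scope and model

placentaSexDE implements a complete bulk RNA-seq pipeline for
characterizing sex differences in gene expression when the sex chromosomes
matter: inference of each sample's sex chromosome complement from marker
genes, complement-specific reference masking, sample quality control,
normalization and moderated differential expression, X–Y gametolog
accounting, and gene-class-stratified comparison of female-to-male
expression ratios across tissues. The motivating application is placental
tissue — an organ whose transcriptome carries the fetal genotype — compared
against adult tissues, but nothing in the machinery is placenta-specific.

The statistical core models log2 counts-per-million per gene as a linear
function of sex plus nuisance covariates (batch, sequencing lane, birth
weight, ancestry principal components), fitted by weighted least squares
with observation-level precision weights derived from the mean–variance
trend, and with per-gene variances shrunk toward a scaled-F prior by
empirical Bayes. The tested contrast is always log2(female/male): sex is
coded with male as the reference level.

# Sex chromosome complement, not reported sex

Reads from X–Y homologous sequence mis-map when a sample is aligned to a
reference whose sex chromosomes do not match its own complement.
The package therefore:

* infers the complement from six marker genes — five Y-linked
  (EIF1AY, KDM5D, UTY, DDX3Y, RPS4Y1) and XIST. A sample is called
  `XY_like` when at least 4 of 5 Y markers exceed a CPM threshold
  (default 1.0), `XX_like` when at most 1 does and XIST exceeds its
  threshold (default 10 CPM), and `ambiguous` otherwise. "Most or all" of
  the Y markers is a qualitative notion; the 4-of-5 operationalization is a
  design choice and both thresholds are exposed as arguments.
* produces hard-masked references: the whole Y replaced by `N` for
  `XX_like` samples, or only the Y pseudoautosomal regions for `XY_like`
  samples (the PARs are duplicated verbatim on X, so leaving both copies
  makes PAR reads multi-map). PAR coordinates are **not** hard-coded — they
  are assembly-specific — and are read from a BED file (0-based half-open
  on disk, converted to 1-based inclusive internally). Masking never
  changes sequence lengths, uses uppercase `N`, preserves soft-masked
  lowercase elsewhere byte-for-byte, and is idempotent.

Sample exclusion follows three rules: post-trimming reads outside
[12.5 M, 90 M]; more than 30% per-sequence GC deviation (consumed as a
precomputed per-sample fraction — the upstream definition of that fraction
is a property of the QC report, not recomputed here); and disagreement
between the inferred complement and the reported sex. The mismatch rule is
implemented as inferred-complement ≠ reported-sex rather than as an MDS
cluster test: it is deterministic and captures the same intent, while MDS
remains available for visual confirmation. Excluding any technical
replicate drops the whole biological sample.

# Normalization and precision weights

* **Technical replicates** are summed before modeling; lanes are recorded
  as the set of contributing lanes.
* **Expression filter**: a gene is kept when FPKM > 1 in *every* sample of
  at least one sex. A laxer group-mean rule is selectable
  (`rule = "mean_of_any_group"`); the all-samples reading is the default
  because it describes which genes can be reported as expressed in a sex.
* **TMM**: the reference sample is the one whose upper-quartile CPM is
  closest to the mean upper-quartile; each factor is the inverse-variance
  (delta-method) weighted mean of per-gene log2 ratios after trimming 30%
  tails by M-value and 5% tails by average log expression, genes with a
  zero in either sample excluded; factors are rescaled to geometric mean 1.
* **log2-CPM**: computed from prior-augmented counts,
  `log2((count + p_j)/(L_j + 2 p_j) * 1e6)` with
  `p_j = 0.25 * L_j / mean(L)` and `L_j` the TMM-effective library size. A
  literal `log2(CPM + 0.25/L)` variant is available behind
  `literalPrior = TRUE` for comparison; taken at face value that formula
  adds a negligible ~7e-9 at 35 M reads and leaves zeros unprotected,
  which is why the prior-augmented-count convention is the default.
* **Precision weights** (voom-style): square-root residual standard
  deviations from an unweighted fit are smoothed against average log2
  count by lowess (span 0.5, 3 robustness iterations — the de-facto
  convention; the trend is insensitive to the span over 0.3–0.7 at these
  gene counts), and each observation's weight is the inverse fourth power
  of the trend at its fitted log2 count. A flat trend yields near-equal
  weights, so the weighting is harmless when counts are deep enough that
  the mean–variance relation has washed out.

# Moderated inference

Per-gene weighted least squares gives residual variances `s²` on
`d = n − p` degrees of freedom. These are modeled as draws from a scaled-F
prior with parameters `(d0, s0²)`, estimated by moment-matching the log
variances (mean and variance of `log s²` against digamma/trigamma
identities; the trigamma inverse is a guarded Newton iteration, tolerance
1e-8). The posterior variance `(d0·s0² + d·s²)/(d0 + d)` feeds the
moderated t-statistic on `d0 + d` degrees of freedom, two-sided p-values,
and BH adjustment at 0.05. Edge cases: when the moment equation implies no
excess variance beyond sampling, the prior is degenerate (`d0 = ∞`) and
the shared variance is the geometric mean of the residual variances (equal
to the common value when they are all identical); genes with exactly zero
residual variance are floored at machine epsilon and flagged. Moderation
is deliberately plain: no robust winsorization and no expression-dependent
prior trend, keeping one global `(d0, s0²)` pair.

Subset analyses (e.g. a curated innate-immune list) re-run the pipeline
from the expression filter onward on the subset, so the filter, TMM
factors and the BH family all refer to the subset.

# Gametolog accounting

For X–Y gametolog pairs, male expression can be quantified as the X-linked
copy alone or as the X + Y sum (the two copies are ancestral homologs with
overlapping function). The package computes both: female X CPM versus male
X CPM, and female X CPM versus male X+Y CPM (females are never summed; Y
expression observed in females is surfaced as a diagnostic). CPM here is
prior-free on TMM-effective library sizes. Each comparison uses a
two-sided Wilcoxon rank-sum test — exact (closed form, or full enumeration
of the permutation distribution of the midrank rank sum when ties are
present and the problem is small) or a tie- and continuity-corrected
normal approximation; a Welch t-test is available behind `test = "ttest"`
for sensitivity. Outcomes are classified per pair at unadjusted p ≤ 0.05
(an across-pairs BH column is emitted for reference but does not drive
classification): `unchanged`, `lost_significance`, `gained_significance`,
or `flipped_direction`. The expression filter for a pair is applied to the
X member or to the male summed series — whether the published analyses
filtered on X, Y or the pair jointly is not stated anywhere we could
verify, so the laxer of the two is used and the choice is visible in the
output. The shipped pair registry is a plain TSV of well-established
pairs that users can replace; it makes no claim to reproduce any specific
curation.

# Cross-tissue ratio correlation

Per tissue, log2 female-to-male ratios are
`log2((F + ε)/(M + ε))` with ε = 0.01 TPM, which keeps ratios finite for
genes expressed in one sex only (Y-linked genes have zero female TPM)
while preserving the sign; genes with zero in both sexes are dropped and
recorded. Gene classes: `all` (expressed genes with ratio data
everywhere), `all_sd` (union of significant genes over the supplied DE
tables), its complement `exclude_sd`, and `all_sd` split into autosomal
(mitochondrial genes grouped with autosomes), X-linked and Y-linked.
Pearson r is computed per tissue × class on the shared finite-ratio genes
(≥ 3 required; Spearman selectable), with p from the t-transform of r and
BH applied within each class column across tissues (`bh_global` pools all
cells instead). Per-column adjustment mirrors how such tissue × class
grids are read — one column, one question.

# The synthetic-data generator

`simulateExperiment()` emulates the structure of a two-sex placental
study; its defaults are the study conditions, not tuning knobs:

* 27 female XX / 23 male XY biological samples, 2 technical replicates
  each, collected in 2 batches balanced by sex; library sizes uniform on
  [25 M, 45 M] reads (the emulated study averaged ~35 M post-trimming).
* Negative-binomial counts with mean `CPM_target × libsize / 1e6` and one
  fixed dispersion. The default dispersion 0.05 (biological CV ≈ 22%) is a
  realistic value for a well-controlled single-tissue human cohort and
  keeps the empirical null log-ratio noise at n = 100 per sex below the
  0.05 log2 tolerance the generator is contracted to
  (`sqrt(2·phi/n)/ln 2 · sqrt(2/π)`); the published dispersion of the real
  data is unknown, so this is a nominal, not fitted, value. Pipeline
  validation simulations use 0.1 where that is the stated condition.
* Marker genes at unambiguous levels: XIST 100 CPM in females / 0.1 in
  males; the five Y markers 20 CPM in males, zero in females. Y-linked
  genes have exactly zero female counts.
* Planted effects of |log2FC| = 2 split symmetrically (±1 log2 unit around
  the base), alternating direction across genes; batch offsets additive on
  the log2 scale (sd 0.1) before sampling, matching their treatment as
  linear-model covariates downstream; gene lengths log-uniform on
  [500, 10000] bp (they only matter for the FPKM filter).
* Gametolog pairs are planted per intended outcome with female X CPM `F`
  and Y fraction `yf`: `unchanged` sets male X to `F/2^effect` (Y silent);
  `lost` sets male X to `F/(1+yf)` so the male X+Y mean equals `F`
  exactly; `flipped` sets male X to `0.6F` with a large `yf`; `gained`
  sets male X to `F` with `yf > 0`.
* Expected per-sample CPM vectors are rescaled to sum to one million
  before sampling so column sums match library sizes; the small
  compositional shift between sexes this induces is exactly the artifact
  TMM corrects.
* The multi-tissue panel anchors sex-linked ratios to the base truth in
  every tissue, while autosomal sex effects are re-drawn per tissue from
  N(0, sd): tissue-specific autosomal effects centred on no effect. This
  is the substantive claim being emulated — sex-linked effects conserved,
  autosomal effects tissue-specific — and it means that with the re-draw
  sd at 0 the per-tissue ratios reproduce the base only for truths whose
  autosomal genes are null.

What the generator does **not** emulate: read-level artifacts (no FASTQ,
no alignment), gene–gene correlation, expression-dependent dispersion
trends, outlier samples beyond the planted QC failures, GC or length
biases within a sample, and X-inactivation mosaicism. Passing tests
therefore show the pipeline's statistical machinery is correct under the
stated model, not that real placental data satisfy that model.

# Problem sizes and reproducibility

The validation suite runs at desk scale: 5,000-gene null experiments at
20 vs 20 across 20 replicate seeds for false-discovery control; 200
planted genes among 3,200 at 23 vs 27 for power; 5,000 variances for
prior recovery; 20 replicate seeds for the gametolog scenarios and for MDS
separation. These sizes give Monte-Carlo error comfortably below every
asserted tolerance. All randomness flows through explicit seeds
(`withr::with_seed`), so every simulation is byte-reproducible; the
identical-seed-identical-output contract is itself under test.
`scripts/acceptance.R` recomputes the headline quantities from scratch at
these sizes from a single command-line seed.

One stochastic property deserves a caveat: a planted
"summing removes the sex difference" gametolog scenario makes the summed
comparison a *true null*, so a calibrated 5%-level test rejects it in
about 1 of 20 replicate seeds. Perfect 20-of-20 classification across
seeds is thus not a property a correct implementation can guarantee;
expected behaviour is 19–20 of 20.

# Known limitations

* One dispersion for all genes; no expression-dependent dispersion trend
  in the generator, and no trended empirical-Bayes prior in the model.
* The GC-deviation exclusion consumes a precomputed per-sample fraction;
  the package does not parse raw QC reports.
* No duplicate-correlation or random-effect modeling of technical
  replicates (they are summed, as in the emulated study design), no
  surrogate-variable estimation, and no gene-set enrichment testing.
* Cross-tissue inputs start at per-tissue, per-sex mean TPM; per-sample
  consortium reprocessing is out of scope.

# A worked micro-example

```{r example}
design <- simulationDesign(nFemale = 10, nMale = 10,
                           nGenesAutosomalNull = 500,
                           nGenesAutosomalSexDE = 30, nGenesXEscape = 10,
                           nGenesYLinked = 6, seed = 42)
sim <- simulateExperiment(design)
sim$countSet

calls <- inferSexComplement(sim$countSet)
table(calls$call, sampleSex(sim$countSet)[calls$sample])

res <- runDEAnalysis(sim$countSet, covariates = c("sex", "batch"))
head(res$table[, c("gene", "logFC_F_vs_M", "adj.P.Val", "chrom_class",
                   "direction")])
res$classCounts
```
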