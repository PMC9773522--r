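# placentaSexDE

Sex differences in bulk RNA-seq expression are dominated by the sex
chromosomes, and getting them right takes more care than a generic
differential-expression run: samples must be aligned to a reference that
matches their sex chromosome complement (whole-Y-masked for XX samples,
Y-PAR-masked for XY samples), the complement itself has to be verified from
expression rather than trusted from metadata, and X–Y gametolog pairs give
different answers depending on whether male expression counts the X copy
alone or the X + Y sum. placentaSexDE packages this whole workflow for
studies such as placental cohorts compared against adult tissue panels —
for bioinformaticians who want the sex-chromosome-aware steps and the
statistical core in one tested, simulation-backed toolbox.

## What it does

* **Sex chromosome complement inference** from five Y-linked markers
  (*EIF1AY*, *KDM5D*, *UTY*, *DDX3Y*, *RPS4Y1*) and *XIST*:
  `XY_like` when ≥ 4/5 Y markers exceed a CPM threshold, `XX_like` when
  ≤ 1 does and XIST is expressed, `ambiguous` otherwise.
* **Reference masking**: whole-Y or Y-PAR hard masking of FASTA files
  (lengths preserved, idempotent, PAR coordinates from a BED file).
* **Sample QC**: read-count window (12.5–90 M), GC-deviation rule (> 30%),
  complement/reported-sex mismatch; excluding one technical replicate
  removes its biological sample.
* **Expression core**: technical-replicate summing, FPKM > 1-in-a-full-sex
  filtering, TMM normalization, log2-CPM with a library-size-scaled prior
  count (0.25), voom-style precision weights, leading-log2FC MDS, and
  batch-effect removal for visualization.
* **Moderated differential expression**: per-gene weighted least squares
  over sex + covariates (batch, lane, birth weight, ancestry PCs), an
  empirical-Bayes scaled-F prior on the variances,

  `s2_post = (d0*s0^2 + d*s2) / (d0 + d)`,  `t = beta / (u * sqrt(s2_post))`,

  with `(d0, s0^2)` from moment-matching the log residual variances, and
  Benjamini–Hochberg adjustment at 0.05. Coefficients are log2
  female/male (male is the reference level).
* **Gametolog analysis**: female X vs male X and female X vs male X+Y
  comparisons per pair (Wilcoxon rank-sum, exact by enumeration for small
  groups even with ties), classified as `unchanged`, `lost_significance`,
  `gained_significance`, or `flipped_direction`.
* **Cross-tissue ratios**: per-tissue `log2((F + 0.01)/(M + 0.01))` from
  mean TPM by sex, Pearson correlation against the placenta per gene class
  (all / excluding sex-DE / all sex-DE / autosomal / X-linked / Y-linked),
  BH-corrected per class column.
* **Synthetic-data generator** with known ground truth (planted effects,
  Y-linked male-only genes, XIST-like marker, X-inactivation escapers,
  gametolog pairs, batches, technical replicates, QC failures, multi-tissue
  panels) so every stage is testable without controlled-access data.

## Worked example

```r
library(placentaSexDE)

design <- simulationDesign(nFemale = 10, nMale = 10,
                           nGenesAutosomalNull = 500,
                           nGenesAutosomalSexDE = 30, nGenesXEscape = 10,
                           nGenesYLinked = 6, seed = 42)
sim <- simulateExperiment(design)
sim$countSet
#> SexCountSet: 552 genes x 40 samples ( female=20, male=20 )

res <- runDEAnalysis(sim$countSet, covariates = c("sex", "batch"))
head(res$table[, c("gene", "logFC_F_vs_M", "adj.P.Val", "chrom_class",
                   "direction")])
#>           gene logFC_F_vs_M adj.P.Val chrom_class direction
#> 552     RPS4Y1        -17.9  1.94e-96           Y   male_up
#> 550        UTY        -18.0  2.30e-96           Y   male_up
#> 544 YLNK_00004        -18.1  2.30e-96           Y   male_up
#> 551      DDX3Y        -17.9  2.88e-96           Y   male_up
#> 543 YLNK_00003        -17.1  5.75e-96           Y   male_up
#> 549      KDM5D        -18.0  6.50e-96           Y   male_up
res$classCounts
#>   chrom_class direction  n
#> 1    autosome female_up 18
#> 2           X female_up 11
#> 4    autosome   male_up 20
#> 6           Y   male_up 11
```

The top hits are Y-linked genes (large negative log2 female/male: zero
female counts against the prior), the X escapers come out female-biased,
and the 30 planted autosomal effects are recovered in both directions.
Summing a Y gametolog into its X partner can invert the inference — here a
female-biased X gene becomes male-biased once the Y copy is counted:

```r
runGametologAnalysis(sim$countSet,
                     pairs = data.frame(x_gene = "XESC_00001",
                                        y_gene = "YLNK_00001"))
#>       x_gene p_x_only direction_x_only p_summed direction_summed  outcome
#> 1 XESC_00001  6.8e-08        female_up  6.8e-08          male_up  flipped_direction
```

See `vignettes/placenta-sex-differences.Rmd` for the model, parameter
choices, and what the simulations do and do not establish.

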