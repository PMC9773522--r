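#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay "assay<-"
#'   assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
#' @importFrom stats approxfun cor cor.test lm.fit lowess median model.matrix
#'   pt quantile rnbinom rnorm runif sd setNames t.test var wilcox.test
#'   contr.sum p.adjust cmdscale dist
#' @importFrom utils read.table write.table head
NULL

CHROM_CLASSES <- c("autosome", "mito", "X", "Y", "X_PAR")

REQUIRED_SAMPLE_COLS <- c("sex", "batch", "lane", "birth_weight_kg",
                          "ancestry_pc1", "ancestry_pc2", "replicate_group")
REQUIRED_GENE_COLS <- c("chrom_class", "length_bp", "gametolog_partner")

## ---------------------------------------------------------------------------
## SexCountSet
## ---------------------------------------------------------------------------

#' Gene-by-sample count container for sex-differential expression analysis
#'
#' `SexCountSet` extends [SummarizedExperiment::SummarizedExperiment] with a
#' single `counts` assay of non-negative integers, per-gene annotation
#' (`chrom_class`, `length_bp`, `gametolog_partner`) in `rowData` and per-sample
#' metadata (`sex`, `batch`, `lane`, `birth_weight_kg`, `ancestry_pc1`,
#' `ancestry_pc2`, `replicate_group`) in `colData`. It is the root object of the
#' pipeline: technical-replicate summing, expression filtering, normalization
#' and differential expression all start from it.
#'
#' @export
setClass("SexCountSet", contains = "SummarizedExperiment")

setValidity("SexCountSet", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (is.null(rownames(cnt)) || is.null(colnames(cnt)))
      msg <- c(msg, "counts must have row and column names")
    else {
      if (anyDuplicated(rownames(cnt))) msg <- c(msg, "gene ids must be unique")
      if (anyDuplicated(colnames(cnt))) msg <- c(msg, "sample ids must be unique")
    }
    if (any(!is.finite(cnt)) || any(cnt < 0))
      msg <- c(msg, "counts must be finite and non-negative")
    else if (any(cnt != round(cnt)))
      msg <- c(msg, "counts must be integral")
  }
  miss <- setdiff(REQUIRED_GENE_COLS, colnames(SummarizedExperiment::rowData(object)))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ", paste(miss, collapse = ", ")))
  missc <- setdiff(REQUIRED_SAMPLE_COLS, colnames(SummarizedExperiment::colData(object)))
  if (length(missc))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(missc, collapse = ", ")))
  if (!length(miss)) {
    cc <- SummarizedExperiment::rowData(object)$chrom_class
    if (!all(cc %in% CHROM_CLASSES))
      msg <- c(msg, paste0("chrom_class values must be one of: ",
                           paste(CHROM_CLASSES, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SexCountSet
#'
#' @param counts integer gene-by-sample matrix with unique row (gene) and
#'   column (sample) names.
#' @param geneAnnotation data.frame keyed by the genes of `counts` (rownames or
#'   a `gene` column) with columns `chrom_class` (one of `autosome`, `mito`,
#'   `X`, `Y`, `X_PAR`), `length_bp` and `gametolog_partner` (`NA` for
#'   unpaired genes). Missing columns are filled with defaults
#'   (`autosome`, 1000 bp, `NA`).
#' @param sampleMetadata data.frame keyed by the samples of `counts` (rownames
#'   or a `sample` column). Missing required columns are filled with neutral
#'   defaults; `replicate_group` defaults to the sample id (all singletons).
#' @return a [SexCountSet-class] object.
#' @examples
#' cnt <- matrix(rpois(20, 10), 5, 4,
#'               dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' cs <- SexCountSet(cnt, sampleMetadata = data.frame(
#'   sample = paste0("s", 1:4), sex = rep(c("female", "male"), each = 2)))
#' sampleSex(cs)
#' @export
SexCountSet <- function(counts, geneAnnotation = NULL, sampleMetadata = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and sample colnames")
  ga <- .keyedFrame(geneAnnotation, rownames(counts), "gene")
  if (is.null(ga$chrom_class)) ga$chrom_class <- "autosome"
  if (is.null(ga$length_bp)) ga$length_bp <- 1000L
  if (is.null(ga$gametolog_partner)) ga$gametolog_partner <- NA_character_
  sm <- .keyedFrame(sampleMetadata, colnames(counts), "sample")
  if (is.null(sm$sex)) sm$sex <- "unknown"
  if (is.null(sm$batch)) sm$batch <- "batch1"
  if (is.null(sm$lane)) sm$lane <- "lane1"
  if (is.null(sm$birth_weight_kg)) sm$birth_weight_kg <- NA_real_
  if (is.null(sm$ancestry_pc1)) sm$ancestry_pc1 <- 0
  if (is.null(sm$ancestry_pc2)) sm$ancestry_pc2 <- 0
  if (is.null(sm$replicate_group)) sm$replicate_group <- colnames(counts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(ga, row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(sm, row.names = colnames(counts)))
  new("SexCountSet", se)
}

## align an optional annotation frame to `keys`, filling absent rows with NA
.keyedFrame <- function(df, keys, keycol) {
  if (is.null(df)) return(data.frame(row.names = keys))
  df <- as.data.frame(df)
  if (keycol %in% colnames(df)) {
    rownames(df) <- df[[keycol]]
    df[[keycol]] <- NULL
  }
  if (is.null(rownames(df)) || !all(keys %in% rownames(df))) {
    missing <- setdiff(keys, rownames(df))
    stop("annotation does not cover: ", paste(head(missing, 5), collapse = ", "))
  }
  df[keys, , drop = FALSE]
}

#' @describeIn SexCountSet raw count matrix
#' @param x,object a `SexCountSet`
#' @export
countsMatrix <- function(x) SummarizedExperiment::assay(x, "counts")

#' @describeIn SexCountSet per-sample sex labels (named character vector)
#' @export
sampleSex <- function(x) {
  stats::setNames(as.character(SummarizedExperiment::colData(x)$sex), colnames(x))
}

#' @describeIn SexCountSet per-gene chromosome class (named character vector)
#' @export
geneClasses <- function(x) {
  stats::setNames(as.character(SummarizedExperiment::rowData(x)$chrom_class), rownames(x))
}

#' @describeIn SexCountSet per-gene length in bp (named numeric vector)
#' @export
geneLengths <- function(x) {
  stats::setNames(as.numeric(SummarizedExperiment::rowData(x)$length_bp), rownames(x))
}

setMethod("show", "SexCountSet", function(object) {
  sx <- table(SummarizedExperiment::colData(object)$sex)
  cat("SexCountSet:", nrow(object), "genes x", ncol(object), "samples (",
      paste(paste0(names(sx), "=", sx), collapse = ", "), ")\n")
  cat("  chrom classes:",
      paste(capture.output(print(table(geneClasses(object))))[2:3], collapse = " /"), "\n")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## NormalizedExpression
## ---------------------------------------------------------------------------

#' Normalized expression container
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a `logCPM` assay
#' (log2 counts-per-million computed from prior-augmented counts against
#' TMM-effective library sizes) and, after [precisionWeights()], a `weights`
#' assay of per-observation inverse-variance precision weights. `colData`
#' carries `lib_size`, `tmm_factor` and `effective_lib_size`; the prior count
#' is stored in `metadata(x)$prior_count`.
#'
#' @export
setClass("NormalizedExpression", contains = "SummarizedExperiment")

setValidity("NormalizedExpression", function(object) {
  msg <- character(0)
  if (!"logCPM" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'logCPM' is required")
  else if (any(!is.finite(SummarizedExperiment::assay(object, "logCPM"))))
    msg <- c(msg, "logCPM must be finite")
  cd <- SummarizedExperiment::colData(object)
  need <- c("lib_size", "tmm_factor", "effective_lib_size")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  else {
    f <- cd$tmm_factor
    if (any(f <= 0)) msg <- c(msg, "tmm factors must be positive")
    else if (abs(mean(log(f))) > 1e-8)
      msg <- c(msg, "tmm factors must have geometric mean 1")
  }
  if ("weights" %in% SummarizedExperiment::assayNames(object)) {
    w <- SummarizedExperiment::assay(object, "weights")
    if (any(!is.finite(w)) || any(w <= 0))
      msg <- c(msg, "weights must be finite and positive")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn NormalizedExpression log2-CPM matrix
#' @param x,object a `NormalizedExpression`
#' @export
logCPM <- function(x) SummarizedExperiment::assay(x, "logCPM")

#' @describeIn NormalizedExpression per-sample TMM scaling factors
#' @export
tmmFactors <- function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$tmm_factor, colnames(x))
}

#' @describeIn NormalizedExpression per-sample TMM-effective library sizes
#' @export
effectiveLibSizes <- function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$effective_lib_size, colnames(x))
}

#' @describeIn NormalizedExpression precision-weight matrix (or NULL before
#'   [precisionWeights()] has been run)
#' @export
precisionWeightMatrix <- function(x) {
  if ("weights" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "weights")
  else NULL
}

setMethod("show", "NormalizedExpression", function(object) {
  cat("NormalizedExpression:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  prior count:", S4Vectors::metadata(object)$prior_count,
      "| weights:", "weights" %in% SummarizedExperiment::assayNames(object), "\n")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## ModeratedFit
## ---------------------------------------------------------------------------

#' Empirical-Bayes moderated per-gene fit
#'
#' Holds, for one contrast, the per-gene weighted-least-squares estimates and
#' the empirical-Bayes moderation that shrinks each residual variance `s2`
#' toward a prior variance `s0sq` with `d0` prior degrees of freedom. The
#' posterior variance is `s2post = (d0*s0sq + df*s2)/(d0 + df)` and the
#' moderated t-statistic is `coef/(stdevUnscaled*sqrt(s2post))` on `d0 + df`
#' degrees of freedom.
#'
#' @slot genes gene identifiers
#' @slot coef per-gene contrast coefficient (log2 female/male)
#' @slot stdevUnscaled per-gene unscaled standard error of the contrast
#' @slot s2 per-gene residual variance
#' @slot df residual degrees of freedom (common to all genes)
#' @slot d0 prior degrees of freedom (may be `Inf`)
#' @slot s0sq prior variance
#' @slot s2post per-gene posterior variance
#' @slot t per-gene moderated t-statistic
#' @slot p two-sided p-value
#' @slot avgLogCPM per-gene mean log2-CPM
#' @slot zeroVarFlag genes whose residual variance was floored at machine eps
#' @slot coefName name of the tested design column
#' @export
setClass("ModeratedFit", representation(
  genes = "character", coef = "numeric", stdevUnscaled = "numeric",
  s2 = "numeric", df = "numeric", d0 = "numeric", s0sq = "numeric",
  s2post = "numeric", t = "numeric", p = "numeric", avgLogCPM = "numeric",
  zeroVarFlag = "logical", coefName = "character"))

setValidity("ModeratedFit", function(object) {
  msg <- character(0)
  n <- length(object@genes)
  for (sl in c("coef", "stdevUnscaled", "s2", "s2post", "t", "p", "avgLogCPM"))
    if (length(slot(object, sl)) != n)
      msg <- c(msg, paste0("slot '", sl, "' must have one value per gene"))
  if (any(object@p < 0 | object@p > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0,1]")
  if (length(object@d0) == 1 && is.finite(object@d0) && object@d0 >= 0 &&
      length(object@s2post) == n && length(object@s2) == n) {
    lo <- pmin(object@s0sq, object@s2) - 1e-8
    hi <- pmax(object@s0sq, object@s2) + 1e-8
    if (any(object@s2post < lo | object@s2post > hi))
      msg <- c(msg, "posterior variances must lie between prior and residual variances")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ModeratedFit", function(object) {
  cat("ModeratedFit:", length(object@genes), "genes | contrast:",
      object@coefName, "\n")
  cat(sprintf("  residual df = %.1f, prior df d0 = %s, prior var s0^2 = %.4g\n",
              object@df, format(object@d0), object@s0sq))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## SimulationDesign
## ---------------------------------------------------------------------------

#' Design of a synthetic placental sex-differences experiment
#'
#' Captures the structure of a two-sex bulk RNA-seq study: sample sizes per
#' sex, gene inventory (autosomal null genes, autosomal sex-DE genes,
#' X-inactivation escapers, Y-linked male-only genes, X-Y gametolog pairs and
#' the six marker genes XIST, EIF1AY, KDM5D, UTY, DDX3Y, RPS4Y1), planted
#' log2 fold change, negative-binomial dispersion, library-size range, batch
#' structure and technical replication. See [simulationDesign()] for defaults.
#'
#' @slot nFemale,nMale samples per sex
#' @slot nGenesAutosomalNull,nGenesAutosomalSexDE,nGenesXEscape,nGenesYLinked
#'   gene counts per class
#' @slot gametologPairs data.frame with columns `x_name`, `y_name`,
#'   `x_base_log2cpm`, `y_fraction_of_x`, `planted_outcome`
#' @slot effectSizeLog2FC planted |log2 female/male| for sex-DE genes
#' @slot nbDispersion negative-binomial dispersion (variance = mu + phi*mu^2)
#' @slot libSizeRange min/max reads per RNA-seq sample
#' @slot nBatches,batchEffectSd batch structure; offsets N(0, sd) on log2 scale
#' @slot replicateCountPerSample technical replicates per biological sample
#' @slot seed RNG seed; identical seed implies byte-identical output
#' @export
setClass("SimulationDesign", representation(
  nFemale = "integer", nMale = "integer",
  nGenesAutosomalNull = "integer", nGenesAutosomalSexDE = "integer",
  nGenesXEscape = "integer", nGenesYLinked = "integer",
  gametologPairs = "data.frame",
  effectSizeLog2FC = "numeric", nbDispersion = "numeric",
  libSizeRange = "numeric", nBatches = "integer", batchEffectSd = "numeric",
  replicateCountPerSample = "integer", seed = "integer"))

GAMETOLOG_OUTCOMES <- c("unchanged", "lost", "flipped", "gained")

setValidity("SimulationDesign", function(object) {
  msg <- character(0)
  cnt <- c(nFemale = object@nFemale, nMale = object@nMale,
           nGenesAutosomalNull = object@nGenesAutosomalNull,
           nGenesAutosomalSexDE = object@nGenesAutosomalSexDE,
           nGenesXEscape = object@nGenesXEscape,
           nGenesYLinked = object@nGenesYLinked,
           nBatches = object@nBatches,
           replicateCountPerSample = object@replicateCountPerSample)
  bad <- names(cnt)[is.na(cnt) | cnt < 0]
  if (length(bad)) msg <- c(msg, paste0("negative or missing count field(s): ",
                                        paste(bad, collapse = ", ")))
  if (!is.na(object@nFemale) && !is.na(object@nMale) &&
      object@nFemale + object@nMale < 4)
    msg <- c(msg, "nFemale + nMale must be at least 4")
  if (object@nBatches < 1) msg <- c(msg, "nBatches must be >= 1")
  if (object@replicateCountPerSample < 1)
    msg <- c(msg, "replicateCountPerSample must be >= 1")
  if (!is.finite(object@nbDispersion) || object@nbDispersion <= 0)
    msg <- c(msg, "nbDispersion must be > 0")
  if (length(object@libSizeRange) != 2 || any(object@libSizeRange <= 0) ||
      object@libSizeRange[1] > object@libSizeRange[2])
    msg <- c(msg, "libSizeRange must be (min, max) with 0 < min <= max")
  if (object@batchEffectSd < 0) msg <- c(msg, "batchEffectSd must be >= 0")
  gp <- object@gametologPairs
  if (nrow(gp)) {
    need <- c("x_name", "y_name", "x_base_log2cpm", "y_fraction_of_x",
              "planted_outcome")
    miss <- setdiff(need, colnames(gp))
    if (length(miss))
      msg <- c(msg, paste0("gametologPairs lacks column(s): ",
                           paste(miss, collapse = ", ")))
    else {
      nm <- c(gp$x_name, gp$y_name)
      if (anyDuplicated(nm)) msg <- c(msg, "gametologPairs: gene names must be unique")
      if (!all(gp$planted_outcome %in% GAMETOLOG_OUTCOMES))
        msg <- c(msg, paste0("gametologPairs: planted_outcome must be one of ",
                             paste(GAMETOLOG_OUTCOMES, collapse = ", ")))
      if (any(gp$y_fraction_of_x < 0))
        msg <- c(msg, "gametologPairs: y_fraction_of_x must be >= 0")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Create a simulation design
#'
#' Defaults emulate the term-placenta study design: 27 female XX and 23 male
#' XY placentas collected in 2 batches with 2 technical replicates each,
#' library sizes around 35 M reads, and a planted sex effect of |log2FC| = 2.
#' The dispersion default 0.05 (biological CV about 22%) is typical of a
#' well-controlled single-tissue human cohort.
#'
#' @param nFemale,nMale samples per sex
#' @param nGenesAutosomalNull,nGenesAutosomalSexDE,nGenesXEscape,nGenesYLinked
#'   number of genes per class (the six marker genes are always added)
#' @param gametologPairs data.frame of X-Y pairs to plant (see
#'   [SimulationDesign-class]); default none
#' @param effectSizeLog2FC planted effect size in log2 units
#' @param nbDispersion negative-binomial dispersion
#' @param libSizeRange numeric length-2, min and max reads per sample
#' @param nBatches,batchEffectSd batch structure
#' @param replicateCountPerSample technical replicates per biological sample
#' @param seed integer RNG seed
#' @return a validated [SimulationDesign-class] object
#' @examples
#' d <- simulationDesign(nFemale = 5, nMale = 5, nGenesAutosomalNull = 100,
#'                       seed = 7)
#' sim <- simulateExperiment(d)
#' sim$countSet
#' @export
simulationDesign <- function(nFemale = 27, nMale = 23,
                             nGenesAutosomalNull = 2000,
                             nGenesAutosomalSexDE = 50,
                             nGenesXEscape = 30,
                             nGenesYLinked = 18,
                             gametologPairs = NULL,
                             effectSizeLog2FC = 2,
                             nbDispersion = 0.05,
                             libSizeRange = c(25e6, 45e6),
                             nBatches = 2,
                             batchEffectSd = 0.1,
                             replicateCountPerSample = 2,
                             seed = 1) {
  if (is.null(gametologPairs))
    gametologPairs <- data.frame(x_name = character(0), y_name = character(0),
                                 x_base_log2cpm = numeric(0),
                                 y_fraction_of_x = numeric(0),
                                 planted_outcome = character(0))
  new("SimulationDesign",
      nFemale = as.integer(nFemale), nMale = as.integer(nMale),
      nGenesAutosomalNull = as.integer(nGenesAutosomalNull),
      nGenesAutosomalSexDE = as.integer(nGenesAutosomalSexDE),
      nGenesXEscape = as.integer(nGenesXEscape),
      nGenesYLinked = as.integer(nGenesYLinked),
      gametologPairs = as.data.frame(gametologPairs),
      effectSizeLog2FC = as.numeric(effectSizeLog2FC),
      nbDispersion = as.numeric(nbDispersion),
      libSizeRange = as.numeric(libSizeRange),
      nBatches = as.integer(nBatches),
      batchEffectSd = as.numeric(batchEffectSd),
      replicateCountPerSample = as.integer(replicateCountPerSample),
      seed = as.integer(seed))
}

setMethod("show", "SimulationDesign", function(object) {
  cat("SimulationDesign:", object@nFemale, "female XX /", object@nMale,
      "male XY biological samples x", object@replicateCountPerSample,
      "replicate(s)\n")
  cat("  genes: null =", object@nGenesAutosomalNull,
      "| autosomal sex-DE =", object@nGenesAutosomalSexDE,
      "| X escape =", object@nGenesXEscape,
      "| Y-linked =", object@nGenesYLinked,
      "| gametolog pairs =", nrow(object@gametologPairs), "\n")
  cat(sprintf("  effect |log2FC| = %g, dispersion = %g, seed = %d\n",
              object@effectSizeLog2FC, object@nbDispersion, object@seed))
  invisible(NULL)
})

#' @importFrom utils capture.output
NULL
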