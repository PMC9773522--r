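## End-to-end sex-differential-expression pipeline over a SexCountSet.

#' Run the sex-differential-expression pipeline
#'
#' Orchestrates the full analysis: technical-replicate summing, expression
#' filtering (FPKM above threshold in every sample of at least one sex),
#' TMM normalization, prior-augmented log2-CPM, voom-style precision
#' weights, per-gene weighted least squares with the requested covariates,
#' empirical-Bayes moderation, and a BH-adjusted result table. When
#' `subset` is given (e.g. an innate-immune gene list) the pipeline from
#' filtering onward is re-run on the subset, so the expression filter, TMM
#' factors and the BH family all refer to the subset analysis.
#'
#' @param x a [SexCountSet-class]
#' @param covariates design covariates (see [buildDesign()]); default sex
#'   only
#' @param alpha significance boundary on the adjusted p-value
#' @param fpkmThreshold,filterRule expression filter (see
#'   [filterExpressed()])
#' @param priorCount log2-CPM prior count
#' @param span lowess span for the precision-weight trend
#' @param subset optional gene subset; must intersect the genes of `x`
#' @param referenceLevels factor reference levels (default male reference,
#'   so coefficients are log2 female/male)
#' @param sumReplicates sum technical replicates first (default TRUE)
#' @return list with `table` (the [deTable()] result), `classCounts`,
#'   `fit` (the [ModeratedFit-class]), `normalized` (the
#'   [NormalizedExpression-class] with weights) and `design`
#' @examples
#' sim <- simulateExperiment(simulationDesign(nFemale = 8, nMale = 8,
#'   nGenesAutosomalNull = 300, nGenesAutosomalSexDE = 20,
#'   replicateCountPerSample = 1, seed = 3))
#' res <- runDEAnalysis(sim$countSet, covariates = "sex")
#' head(res$table)
#' @export
runDEAnalysis <- function(x, covariates = "sex", alpha = 0.05,
                          fpkmThreshold = 1,
                          filterRule = "all_of_any_group",
                          priorCount = 0.25, span = 0.5, subset = NULL,
                          referenceLevels = list(sex = "male"),
                          sumReplicates = TRUE) {
  stopifnot(is(x, "SexCountSet"))
  if (sumReplicates) x <- sumTechnicalReplicates(x)
  if (!is.null(subset)) {
    subset <- intersect(subset, rownames(x))
    if (!length(subset)) stop("subset does not intersect the genes of x")
    x <- x[subset, ]
  }
  filt <- filterExpressed(x, fpkmThreshold = fpkmThreshold,
                          rule = filterRule)
  if (!nrow(filt)) stop("no gene passed the expression filter")
  norm <- normalizeExpression(filt, priorCount = priorCount)
  design <- buildDesign(
    as.data.frame(SummarizedExperiment::colData(filt)),
    covariates = covariates, referenceLevels = referenceLevels)
  norm <- precisionWeights(norm, design, span = span)
  fit <- fitGeneModels(logCPM(norm), precisionWeightMatrix(norm), design)
  mfit <- ebayesModerate(fit)
  tab <- deTable(mfit,
                 annotation = as.data.frame(
                   SummarizedExperiment::rowData(filt)),
                 alpha = alpha)
  list(table = tab, classCounts = summarizeDEByClass(tab), fit = mfit,
       normalized = norm, design = design)
}
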