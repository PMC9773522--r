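## Expression core: technical-replicate summing, CPM/FPKM, expression
## filtering, TMM normalization, prior-augmented log2-CPM, voom-style
## precision weights, leading-logFC MDS and batch-effect removal.

.countInput <- function(x) {
  if (is(x, "SexCountSet")) countsMatrix(x) else as.matrix(x)
}

#' Sum technical replicates into biological samples
#'
#' Columns sharing a `replicate_group` are summed element-wise into a single
#' column named after the group. Metadata must agree within a group except
#' for `lane`, which is recorded as the comma-joined sorted set of
#' contributing lanes. Total counts are conserved and the gene set is
#' unchanged.
#'
#' @param x a [SexCountSet-class] with `replicate_group` set for every sample
#' @return a [SexCountSet-class] with one column per replicate group
#' @export
sumTechnicalReplicates <- function(x) {
  stopifnot(is(x, "SexCountSet"))
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  grp <- as.character(cd$replicate_group)
  if (any(is.na(grp) | grp == ""))
    stop("replicate_group must be set for every sample")
  groups <- unique(grp)
  for (colname in c("sex", "batch")) {
    nlev <- tapply(as.character(cd[[colname]]), grp,
                   function(v) length(unique(v)))
    bad <- names(nlev)[nlev > 1]
    if (length(bad))
      stop("conflicting '", colname, "' within replicate group(s): ",
           paste(bad, collapse = ", "))
  }
  cnt <- countsMatrix(x)
  summed <- vapply(groups, function(g)
    rowSums(cnt[, grp == g, drop = FALSE]), numeric(nrow(cnt)))
  colnames(summed) <- groups
  first <- match(groups, grp)
  meta <- cd[first, , drop = FALSE]
  meta$lane <- vapply(groups, function(g)
    paste(sort(unique(as.character(cd$lane[grp == g]))), collapse = ","),
    character(1))
  meta$replicate_group <- groups
  rownames(meta) <- groups
  SexCountSet(summed,
              geneAnnotation = as.data.frame(
                SummarizedExperiment::rowData(x)),
              sampleMetadata = meta)
}

#' Counts per million
#'
#' With `priorCount = 0` each column of the result sums to exactly one
#' million. Library sizes default to column sums; pass TMM-effective sizes
#' (see [tmmNormalize()]) for normalized CPM.
#'
#' @param x count matrix or [SexCountSet-class]
#' @param priorCount count added to every entry before scaling (default 0)
#' @param libSizes optional per-sample library sizes (defaults to column
#'   sums)
#' @return numeric matrix of CPM values
#' @export
computeCPM <- function(x, priorCount = 0, libSizes = NULL) {
  cnt <- .countInput(x)
  if (is.null(libSizes)) libSizes <- colSums(cnt)
  zero <- libSizes <= 0
  if (any(zero))
    stop("zero-depth sample(s): ", paste(colnames(cnt)[zero], collapse = ", "))
  sweep(cnt + priorCount, 2, libSizes, "/") * 1e6
}

#' Fragments per kilobase per million
#'
#' `FPKM = count / (length_kb * depth_millions)`; used only for the
#' expression filter, matching the study's FPKM > 1 rule.
#'
#' @param x count matrix or [SexCountSet-class]
#' @param lengths per-gene lengths in bp (taken from `rowData` for a
#'   `SexCountSet`)
#' @param libSizes optional library sizes (default column sums)
#' @return numeric matrix of FPKM values
#' @export
computeFPKM <- function(x, lengths = NULL, libSizes = NULL) {
  cnt <- .countInput(x)
  if (is.null(lengths) && is(x, "SexCountSet")) lengths <- geneLengths(x)
  if (is.null(lengths)) stop("gene lengths are required for FPKM")
  lengths <- lengths[rownames(cnt)]
  if (any(is.na(lengths) | lengths <= 0))
    stop("missing or non-positive gene length(s)")
  if (is.null(libSizes)) libSizes <- colSums(cnt)
  sweep(cnt / (lengths / 1e3), 2, libSizes / 1e6, "/")
}

#' Filter to expressed genes
#'
#' Default rule (`all_of_any_group`): a gene is kept iff its FPKM exceeds
#' `fpkmThreshold` in every sample of at least one group — the "FPKM > 1 in
#' at least all the male XY or all female XX samples" criterion.
#' `mean_of_any_group` keeps a gene when any group's mean FPKM exceeds the
#' threshold. The operation is idempotent.
#'
#' @param x a [SexCountSet-class]
#' @param groups named list of sample-id vectors partitioning the samples,
#'   or a factor/vector over samples; defaults to the `sex` column
#' @param fpkmThreshold expression threshold (default 1)
#' @param rule `"all_of_any_group"` (default) or `"mean_of_any_group"`
#' @return the filtered [SexCountSet-class]; kept genes are its rownames
#' @export
filterExpressed <- function(x, groups = NULL, fpkmThreshold = 1,
                            rule = c("all_of_any_group", "mean_of_any_group")) {
  stopifnot(is(x, "SexCountSet"))
  rule <- match.arg(rule)
  samples <- colnames(x)
  if (is.null(groups))
    groups <- split(samples, sampleSex(x))
  if (!is.list(groups)) groups <- split(samples, groups)
  if (any(lengths(groups) == 0)) stop("empty group in partition")
  flat <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(flat) || !setequal(flat, samples))
    stop("groups must partition the samples")
  fpkm <- computeFPKM(x)
  keep <- Reduce(`|`, lapply(groups, function(g) {
    sub <- fpkm[, g, drop = FALSE]
    if (rule == "all_of_any_group") rowSums(sub > fpkmThreshold) == ncol(sub)
    else rowMeans(sub) > fpkmThreshold
  }))
  x[keep, ]
}

## single-pair TMM factor: precision-weighted doubly trimmed mean of M-values
.tmmFactorPair <- function(obs, ref, libObs, libRef, logratioTrim, absTrim) {
  logR <- log2((obs / libObs) / (ref / libRef))
  absE <- (log2(obs / libObs) + log2(ref / libRef)) / 2
  v <- (libObs - obs) / libObs / obs + (libRef - ref) / libRef / ref
  fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratioTrim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * absTrim) + 1; hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
          rank(absE) >= loS & rank(absE) <= hiS
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: the reference sample is the one whose
#' upper-quartile CPM is closest to the mean upper-quartile; each sample's
#' factor is `2^f` where `f` is the inverse-variance (delta-method) weighted
#' mean of per-gene log2 ratios against the reference after trimming the
#' most extreme `logratioTrim` fraction by M-value and `absTrim` by average
#' log expression (genes with a zero count in either sample are excluded).
#' Factors are rescaled so their geometric mean is exactly 1;
#' `effective_lib_size = lib_size * tmm_factor`.
#'
#' @param x count matrix or [SexCountSet-class] (filtered matrix recommended)
#' @param logratioTrim fraction trimmed from each tail of the M-values
#' @param absTrim fraction trimmed from each tail of the A-values
#' @return data.frame with `sample`, `lib_size`, `tmm_factor`,
#'   `effective_lib_size`
#' @export
tmmNormalize <- function(x, logratioTrim = 0.30, absTrim = 0.05) {
  cnt <- .countInput(x)
  if (ncol(cnt) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(cnt)
  if (any(lib <= 0)) stop("zero-depth sample(s)")
  f75 <- vapply(seq_len(ncol(cnt)), function(j)
    stats::quantile(cnt[, j] / lib[j], 0.75, names = FALSE), numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- vapply(seq_len(ncol(cnt)), function(j)
    .tmmFactorPair(cnt[, j], cnt[, ref], lib[j], lib[ref],
                   logratioTrim, absTrim), numeric(1))
  fac <- fac / exp(mean(log(fac)))
  data.frame(sample = colnames(cnt), lib_size = lib, tmm_factor = fac,
             effective_lib_size = lib * fac, row.names = colnames(cnt),
             stringsAsFactors = FALSE)
}

.effLibSizes <- function(cnt, factors) {
  if (is.null(factors)) return(colSums(cnt))
  if (is.data.frame(factors)) {
    if (!all(colnames(cnt) %in% factors$sample))
      stop("normalization factors do not cover all samples")
    return(factors$effective_lib_size[match(colnames(cnt), factors$sample)])
  }
  if (is.numeric(factors) && length(factors) == ncol(cnt))
    return(colSums(cnt) * factors)
  stop("factors must be a tmmNormalize() result or per-sample numeric factors")
}

#' Log2-CPM with a library-size-scaled prior count
#'
#' Computes `log2` CPM from prior-augmented counts against effective library
#' sizes: per sample `j`, `log2((count + p_j) / (L_j + 2 p_j) * 1e6)` with
#' `p_j = priorCount * L_j / mean(L)`, so zero counts map to a finite value
#' and the transform is monotone within a sample. Setting
#' `literalPrior = TRUE` instead computes `log2(CPM + priorCount / L)` — the
#' naive reading under which the prior is negligible and zeros stay
#' `-Inf`-prone — for comparison only.
#'
#' @param x count matrix or [SexCountSet-class]
#' @param factors result of [tmmNormalize()] (or per-sample numeric
#'   factors); `NULL` uses raw column sums
#' @param priorCount prior count (default 0.25); must be positive
#' @param literalPrior use the literal `log2(CPM + prior/L)` formula
#' @return matrix of log2-CPM values with attributes `effectiveLibSize` and
#'   `priorCount`
#' @export
logCPMTransform <- function(x, factors = NULL, priorCount = 0.25,
                            literalPrior = FALSE) {
  if (priorCount <= 0) stop("priorCount must be positive")
  cnt <- .countInput(x)
  eff <- .effLibSizes(cnt, factors)
  if (literalPrior) {
    out <- log2(sweep(sweep(cnt, 2, eff, "/") * 1e6, 2, priorCount / eff, "+"))
  } else {
    ps <- priorCount * eff / mean(eff)
    out <- log2(sweep(sweep(cnt, 2, ps, "+"), 2, eff + 2 * ps, "/") * 1e6)
  }
  attr(out, "effectiveLibSize") <- stats::setNames(eff, colnames(cnt))
  attr(out, "priorCount") <- priorCount
  out
}

#' Normalize a count set to log2-CPM
#'
#' Convenience pipeline step: TMM factors + prior-augmented log2-CPM wrapped
#' into a [NormalizedExpression-class]. Run [precisionWeights()] afterwards
#' to add the voom-style weights assay.
#'
#' @param x a [SexCountSet-class]
#' @param priorCount prior count for the log transform
#' @param logratioTrim,absTrim TMM trim fractions
#' @return a [NormalizedExpression-class]
#' @export
normalizeExpression <- function(x, priorCount = 0.25, logratioTrim = 0.30,
                                absTrim = 0.05) {
  stopifnot(is(x, "SexCountSet"))
  tmm <- tmmNormalize(x, logratioTrim, absTrim)
  E <- logCPMTransform(x, tmm, priorCount)
  cd <- SummarizedExperiment::colData(x)
  cd$lib_size <- tmm$lib_size
  cd$tmm_factor <- tmm$tmm_factor
  cd$effective_lib_size <- tmm$effective_lib_size
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logCPM = unclass(E)[, , drop = FALSE]),
    rowData = SummarizedExperiment::rowData(x), colData = cd)
  S4Vectors::metadata(se)$prior_count <- priorCount
  new("NormalizedExpression", se)
}

## voom-style weights on a plain matrix; lib sizes needed to map fitted
## log-CPM back to log-counts where the trend lives
.voomWeights <- function(E, design, libSizes, span) {
  n <- nrow(E); m <- ncol(E); p <- qr(design)$rank
  if (p < ncol(design)) stop("design matrix is not of full rank")
  df <- m - ncol(design)
  if (df < 1) stop("at least 1 residual degree of freedom is required")
  fit <- stats::lm.fit(design, t(E))
  sigma <- sqrt(colSums(as.matrix(fit$residuals)^2) / df)
  sx <- rowMeans(E) + mean(log2(libSizes + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  l <- stats::lowess(sx, sy, f = span, iter = 3)
  trend <- stats::approxfun(l, rule = 2, ties = mean)
  fitted <- t(design %*% fit$coefficients)  # n x m fitted log-CPM
  fittedLogCount <- sweep(fitted, 2, log2(libSizes + 1) - log2(1e6), "+")
  w <- 1 / pmax(trend(fittedLogCount), 1e-10)^4
  dim(w) <- dim(E); dimnames(w) <- dimnames(E)
  list(weights = w, trend = data.frame(avg_log_count = sx, sqrt_sd = sy))
}

#' Voom-style precision weights
#'
#' Per-gene square-root residual standard deviations from an unweighted fit
#' of the design are regressed on average log2 count with lowess
#' (span `span`, 3 robustness iterations); every observation's weight is the
#' inverse fourth power of the trend evaluated at its fitted log2 count.
#' A flat mean-variance trend therefore yields near-equal weights, and all
#' weights are positive and finite.
#'
#' @param x a [NormalizedExpression-class] (returned with a `weights`
#'   assay added) or a log2-CPM matrix (returns a list)
#' @param design design matrix from [buildDesign()]
#' @param span lowess span (default 0.5)
#' @param libSizes effective library sizes; taken from the object or the
#'   matrix's `effectiveLibSize` attribute when missing
#' @return the updated `NormalizedExpression`, or for matrix input a list
#'   with `weights` and the fitted `trend`
#' @export
precisionWeights <- function(x, design, span = 0.5, libSizes = NULL) {
  if (is(x, "NormalizedExpression")) {
    res <- .voomWeights(logCPM(x), design, effectiveLibSizes(x), span)
    SummarizedExperiment::assay(x, "weights") <- res$weights
    S4Vectors::metadata(x)$voom_trend <- res$trend
    methods::validObject(x)
    return(x)
  }
  E <- as.matrix(x)
  if (is.null(libSizes)) libSizes <- attr(x, "effectiveLibSize")
  if (is.null(libSizes))
    stop("libSizes are required when x is a plain matrix")
  .voomWeights(E, design, libSizes, span)
}

#' Multidimensional scaling on leading log2 fold changes
#'
#' The distance between two samples is the root-mean-square difference of
#' their log2-CPM over the selected genes — an approximation of the typical
#' leading log2 fold change. Under `common` selection the `nTop` genes with
#' the largest standard deviation across all samples are used for every
#' pair; under `pairwise` each pair uses its own `nTop` genes with the
#' largest absolute difference. Coordinates come from classical metric
#' scaling (eigendecomposition of the double-centred squared-distance
#' matrix); they are sign-indeterminate, so the first non-zero coordinate of
#' each dimension is fixed non-negative.
#'
#' @param E log2-CPM matrix (genes x samples), at least 3 samples
#' @param nTop number of genes used per (pair of) sample(s)
#' @param geneSelection `"common"` (default) or `"pairwise"`
#' @param k number of dimensions (default 2)
#' @return list with `coordinates` (samples x k), `distance` (sample
#'   distance matrix) and `eig` (eigenvalues)
#' @export
leadingLogFCMDS <- function(E, nTop = 500,
                            geneSelection = c("common", "pairwise"), k = 2) {
  geneSelection <- match.arg(geneSelection)
  E <- as.matrix(E)
  m <- ncol(E)
  if (m < 3) stop("MDS needs at least 3 samples")
  if (nTop < 1) stop("nTop must be >= 1")
  nTop <- min(nTop, nrow(E))
  D <- matrix(0, m, m, dimnames = list(colnames(E), colnames(E)))
  if (geneSelection == "common") {
    ctr <- E - rowMeans(E)
    sds <- sqrt(rowSums(ctr^2) / (m - 1))
    top <- order(sds, decreasing = TRUE)[seq_len(nTop)]
    sub <- E[top, , drop = FALSE]
    D <- as.matrix(stats::dist(t(sub))) / sqrt(nTop)
  } else {
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      d <- abs(E[, i] - E[, j])
      top <- sort(d, decreasing = TRUE)[seq_len(nTop)]
      D[i, j] <- D[j, i] <- sqrt(mean(top^2))
    }
  }
  mds <- stats::cmdscale(stats::as.dist(D), k = min(k, m - 1), eig = TRUE)
  pts <- mds$points
  if (ncol(pts) < k)
    pts <- cbind(pts, matrix(0, m, k - ncol(pts)))
  for (d in seq_len(ncol(pts))) {
    nz <- which(abs(pts[, d]) > 1e-12)
    if (length(nz) && pts[nz[1], d] < 0) pts[, d] <- -pts[, d]
  }
  colnames(pts) <- paste0("dim", seq_len(ncol(pts)))
  rownames(pts) <- colnames(E)
  list(coordinates = pts, distance = D, eig = mds$eig)
}

#' Remove batch effects from log expression (visualization only)
#'
#' Fits, per gene, a linear model containing the retained design plus
#' sum-coded batch indicators, and subtracts only the fitted batch terms.
#' Intended solely for visualization (e.g. before MDS); batch stays in the
#' statistical model for testing.
#'
#' @param E log2-CPM matrix (genes x samples)
#' @param batch per-sample batch labels (a factor with >= 2 levels does
#'   anything; a single level returns `E` unchanged)
#' @param design optional design of effects to retain (default intercept)
#' @return adjusted log2-CPM matrix
#' @export
removeBatchEffects <- function(E, batch, design = NULL) {
  E <- as.matrix(E)
  batch <- droplevels(as.factor(batch))
  if (length(batch) != ncol(E))
    stop("batch must have one label per sample")
  if (nlevels(batch) < 2) return(E)
  if (is.null(design)) design <- matrix(1, ncol(E), 1)
  stats::contrasts(batch) <- stats::contr.sum(nlevels(batch))
  Xb <- stats::model.matrix(~batch)[, -1, drop = FALSE]
  X <- cbind(design, Xb)
  if (qr(X)$rank < ncol(X))
    stop("batch is confounded with the retained design")
  fit <- stats::lm.fit(X, t(E))
  beta <- as.matrix(fit$coefficients)[ncol(design) + seq_len(ncol(Xb)), ,
                                      drop = FALSE]
  beta[is.na(beta)] <- 0
  E - t(Xb %*% beta)
}
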