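## Differential-expression core: covariate design matrices, per-gene weighted
## least squares, empirical-Bayes variance moderation, Benjamini-Hochberg
## adjustment, and result tables with per-chromosome-class summaries.

#' Build a covariate design matrix
#'
#' Treatment (reference-level) coding over the requested covariates. By
#' default sex is coded with male as the reference, so the `sexfemale`
#' column is the log2 female/male contrast. Factor covariates with a single
#' observed level are dropped with a warning; rank deficiency (e.g. batch
#' perfectly confounded with sex) is an error naming the collinear columns.
#'
#' @param metadata per-sample data.frame (or `colData`) containing the
#'   covariate columns, one row per kept sample
#' @param covariates character vector of column names; the first factor
#'   named `sex` defines the tested contrast
#' @param referenceLevels named list of reference levels for factor
#'   covariates (default `list(sex = "male")`)
#' @return design matrix with attributes `contrast` (name of the sex
#'   contrast column) and `covariates`
#' @examples
#' md <- data.frame(sex = rep(c("male", "female"), 3),
#'                  batch = rep(c("b1", "b2"), each = 3))
#' buildDesign(md, c("sex", "batch"))
#' @export
buildDesign <- function(metadata,
                        covariates = c("sex", "batch", "lane",
                                       "birth_weight_kg", "ancestry_pc1",
                                       "ancestry_pc2"),
                        referenceLevels = list(sex = "male")) {
  metadata <- as.data.frame(metadata)
  miss <- setdiff(covariates, colnames(metadata))
  if (length(miss))
    stop("covariate column(s) missing: ", paste(miss, collapse = ", "))
  sub <- metadata[, covariates, drop = FALSE]
  if (anyNA(sub))
    stop("missing values among covariates: ",
         paste(covariates[vapply(sub, anyNA, logical(1))], collapse = ", "))
  keep <- character(0)
  for (v in covariates) {
    col <- sub[[v]]
    if (is.character(col) || is.factor(col)) {
      col <- droplevels(as.factor(col))
      if (!is.null(referenceLevels[[v]])) {
        if (!referenceLevels[[v]] %in% levels(col))
          stop("reference level '", referenceLevels[[v]],
               "' not present in '", v, "'")
        col <- stats::relevel(col, referenceLevels[[v]])
      }
      if (nlevels(col) < 2) {
        warning("dropping single-level covariate '", v, "'")
        next
      }
      sub[[v]] <- col
    }
    keep <- c(keep, v)
  }
  if (!length(keep)) stop("no usable covariates")
  form <- stats::as.formula(paste("~", paste(keep, collapse = " + ")))
  X <- stats::model.matrix(form, data = sub)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    collinear <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(collinear, collapse = ", "))
  }
  rownames(X) <- rownames(metadata)
  contrast <- grep("^sex", colnames(X), value = TRUE)
  attr(X, "contrast") <- if (length(contrast)) contrast[1] else NULL
  attr(X, "covariates") <- keep
  X
}

#' Per-gene weighted least squares
#'
#' Fits one linear model per gene by weighted least squares, with optional
#' per-observation precision weights (all 1 reduces to ordinary least
#' squares). The residual degrees of freedom are `n - p` for every gene.
#'
#' @param E log2-CPM matrix (genes x samples)
#' @param weights per-observation weight matrix of the same shape, or NULL
#' @param design design matrix from [buildDesign()]
#' @param coefName tested coefficient (defaults to the design's `contrast`
#'   attribute)
#' @return list of class `geneFit`: `genes`, `coef`, `stdevUnscaled`, `s2`,
#'   `df`, `avgLogCPM`, `coefName`
#' @export
fitGeneModels <- function(E, weights = NULL, design,
                          coefName = attr(design, "contrast")) {
  E <- as.matrix(E)
  if (any(!is.finite(E))) stop("non-finite expression values")
  n <- nrow(E); m <- ncol(E); p <- ncol(design)
  if (nrow(design) != m) stop("design rows must match samples")
  df <- m - p
  if (df < 1) stop("at least 1 residual degree of freedom is required")
  if (is.null(coefName)) stop("specify the tested coefficient via 'coefName'")
  ci <- match(coefName, colnames(design))
  if (is.na(ci)) stop("coefficient '", coefName, "' not in design")
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!all(dim(weights) == dim(E)))
      stop("weights must match the expression matrix")
    if (any(!is.finite(weights)) || any(weights <= 0))
      stop("weights must be finite and positive")
  }
  coef <- su <- s2 <- numeric(n)
  if (is.null(weights)) {
    fit <- stats::lm.fit(design, t(E))
    cf <- as.matrix(fit$coefficients)
    res <- as.matrix(fit$residuals)
    xtxi <- chol2inv(chol(crossprod(design)))
    coef <- cf[ci, ]
    su <- rep(sqrt(xtxi[ci, ci]), n)
    s2 <- colSums(res^2) / df
  } else {
    for (g in seq_len(n)) {
      sw <- sqrt(weights[g, ])
      Xw <- design * sw
      yw <- E[g, ] * sw
      xtxi <- chol2inv(chol(crossprod(Xw)))
      b <- drop(xtxi %*% crossprod(Xw, yw))
      r <- yw - drop(Xw %*% b)
      coef[g] <- b[ci]
      su[g] <- sqrt(xtxi[ci, ci])
      s2[g] <- sum(r^2) / df
    }
  }
  structure(list(genes = rownames(E), coef = unname(coef),
                 stdevUnscaled = unname(su), s2 = unname(s2), df = df,
                 avgLogCPM = unname(rowMeans(E)), coefName = coefName),
            class = "geneFit")
}

## Newton inversion of the trigamma function on (0, Inf)
.trigammaInverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(NaN)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (iter in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2)
      y <- y + dif
      if (-dif / y < 1e-8) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderation of residual variances
#'
#' Models the per-gene residual variances as draws from a scaled-F prior and
#' estimates the prior degrees of freedom `d0` and prior variance `s0^2` by
#' moment-matching the log residual variances (digamma/trigamma identities;
#' trigamma inverse by guarded Newton iteration). Each gene's posterior
#' variance `(d0*s0^2 + df*s2)/(d0 + df)` then shrinks the residual variance
#' toward the prior; the moderated t-statistic uses `d0 + df` degrees of
#' freedom. When the moment equation implies non-positive excess variance
#' the prior is degenerate: `d0 = Inf` and the posterior equals `s0^2`.
#' Genes with zero residual variance are floored at machine epsilon and
#' flagged.
#'
#' @param fit a `geneFit` from [fitGeneModels()]
#' @param priorDf override the estimated `d0` (0 recovers the classical
#'   per-gene t-test; `Inf` pools fully to `priorVar`)
#' @param priorVar prior variance used with an overridden `priorDf`
#' @return a [ModeratedFit-class]
#' @export
ebayesModerate <- function(fit, priorDf = NULL, priorVar = NULL) {
  stopifnot(inherits(fit, "geneFit"))
  s2 <- fit$s2
  d <- fit$df
  if (length(s2) < 10 && is.null(priorDf))
    stop("at least 10 genes are required to estimate the prior")
  if (all(s2 == 0)) stop("all residual variances are zero")
  zeroVar <- s2 <= 0
  s2[zeroVar] <- .Machine$double.eps
  if (is.null(priorDf)) {
    z <- log(s2)
    e <- z - digamma(d / 2) + log(d / 2)
    emean <- mean(e)
    evar <- stats::var(e) - trigamma(d / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * .trigammaInverse(evar)
      s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      ## degenerate prior: no excess variance beyond sampling, so every gene
      ## shares one variance — the geometric mean of the residual variances
      ## (equal to the common value when they are all identical)
      d0 <- Inf
      s0sq <- exp(mean(z))
    }
  } else {
    d0 <- priorDf
    s0sq <- if (!is.null(priorVar)) priorVar
            else if (is.finite(d0) && d0 == 0) mean(s2)
            else exp(mean(log(s2) - digamma(d / 2) + log(d / 2)))
  }
  s2post <- if (is.infinite(d0)) rep(s0sq, length(s2))
            else (d0 * s0sq + d * s2) / (d0 + d)
  tstat <- fit$coef / (fit$stdevUnscaled * sqrt(s2post))
  dfTotal <- d0 + d
  pval <- 2 * stats::pt(-abs(tstat), df = dfTotal)
  new("ModeratedFit", genes = fit$genes, coef = fit$coef,
      stdevUnscaled = fit$stdevUnscaled, s2 = s2, df = d, d0 = d0,
      s0sq = s0sq, s2post = s2post, t = tstat, p = pval,
      avgLogCPM = fit$avgLogCPM, zeroVarFlag = zeroVar,
      coefName = fit$coefName)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values: monotone, capped at 1, input order preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return adjusted p-values in the input order
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Differential-expression result table
#'
#' Assembles the per-gene table (log2 female/male coefficient, moderated t,
#' raw and BH-adjusted p, direction) sorted by adjusted then raw p-value.
#' When `subset` is given the table is restricted to those genes and the BH
#' adjustment is recomputed over the subset only, matching a targeted
#' (e.g. innate-immune) analysis. Use [summarizeDEByClass()] for the
#' per-chromosome-class significance counts.
#'
#' @param mfit a [ModeratedFit-class]
#' @param annotation data.frame keyed by gene with a `chrom_class` column
#'   (e.g. `rowData` of the analyzed [SexCountSet-class])
#' @param alpha significance boundary on the adjusted p-value (default 0.05)
#' @param subset optional character vector of genes; must intersect the
#'   analyzed genes
#' @return data.frame with columns `gene`, `logFC_F_vs_M`, `AveLogCPM`, `t`,
#'   `P.Value`, `adj.P.Val`, `chrom_class`, `direction`, `significant`
#' @export
deTable <- function(mfit, annotation = NULL, alpha = 0.05, subset = NULL) {
  stopifnot(is(mfit, "ModeratedFit"))
  idx <- seq_along(mfit@genes)
  if (!is.null(subset)) {
    idx <- which(mfit@genes %in% subset)
    if (!length(idx)) stop("subset does not intersect the analyzed genes")
  }
  genes <- mfit@genes[idx]
  cc <- rep(NA_character_, length(genes))
  if (!is.null(annotation)) {
    anno <- as.data.frame(annotation)
    key <- if ("gene" %in% colnames(anno)) anno$gene else rownames(anno)
    found <- match(genes, key)
    cc[!is.na(found)] <- as.character(anno$chrom_class[found[!is.na(found)]])
  }
  tab <- data.frame(
    gene = genes,
    logFC_F_vs_M = mfit@coef[idx],
    AveLogCPM = mfit@avgLogCPM[idx],
    t = mfit@t[idx],
    P.Value = mfit@p[idx],
    adj.P.Val = bhAdjust(mfit@p[idx]),
    chrom_class = cc,
    direction = ifelse(mfit@coef[idx] > 0, "female_up", "male_up"),
    zero_var_floored = mfit@zeroVarFlag[idx],
    stringsAsFactors = FALSE)
  tab$significant <- tab$adj.P.Val <= alpha
  tab[order(tab$adj.P.Val, tab$P.Value), , drop = FALSE]
}

#' Significant-gene counts by chromosome class and direction
#'
#' @param deTab a table from [deTable()]
#' @return data.frame of counts per (`chrom_class`, `direction`) among
#'   significant genes
#' @export
summarizeDEByClass <- function(deTab) {
  sig <- deTab[deTab$significant, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(chrom_class = character(0), direction = character(0),
                      n = integer(0)))
  agg <- as.data.frame(table(chrom_class = sig$chrom_class,
                             direction = sig$direction))
  names(agg)[3] <- "n"
  agg[agg$n > 0, , drop = FALSE]
}
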