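## X-Y gametolog expression analysis: compare female X-linked expression with
## male X-linked expression alone versus male X-plus-Y summed expression, and
## classify how the inference changes between the two accounting schemes.

#' Packaged X-Y gametolog pair registry
#'
#' A registry of well-established human X-Y gametolog pairs shipped as a
#' plain TSV (`x_gene`, `y_gene`) under `extdata`. Users analyzing their own
#' data can pass any replacement table of the same shape to
#' [runGametologAnalysis()].
#'
#' @return data.frame with columns `x_gene` and `y_gene`
#' @export
gametologPairs <- function() {
  path <- system.file("extdata", "gametolog_pairs.tsv",
                      package = "placentaSexDE", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum test with explicit method control
#'
#' Two-sided rank-sum test of `a` versus `b`. `auto` uses exact enumeration
#' when both groups have at most 10 observations and there are no ties,
#' otherwise the normal approximation with tie and continuity correction.
#' `exact` forces the exact two-sided p-value: the closed-form null
#' distribution for untied data, or full enumeration of the permutation
#' distribution of the (midrank) rank sum when ties are present (feasible
#' for small groups; larger tied problems fall back to the corrected
#' approximation with a warning). The direction is the shift of the medians
#' (`none` when equal).
#'
#' @param a,b numeric vectors, each with at least 2 observations
#' @param method `"auto"`, `"exact"` or `"normal_approx_cc"`
#' @return list with `p` (two-sided), `direction` (`"first_up"`,
#'   `"second_up"` or `"none"`) and `method` actually used
#' @examples
#' rankSumTest(c(1, 2, 3), c(10, 11, 12), method = "exact")$p  # 0.1
#' @export
rankSumTest <- function(a, b, method = c("auto", "exact",
                                         "normal_approx_cc")) {
  method <- match.arg(method)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 observations")
  if (any(!is.finite(c(a, b)))) stop("non-finite values")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- switch(method,
                  auto = length(a) <= 10 && length(b) <= 10 && !ties,
                  exact = TRUE,
                  normal_approx_cc = FALSE)
  usedMethod <- "normal_approx_cc"
  if (exact && ties && choose(length(a) + length(b), length(a)) > 5e5) {
    warning("tied groups too large for enumeration; ",
            "using the corrected normal approximation")
    exact <- FALSE
  }
  if (exact && ties) {
    ## permutation distribution of the midrank rank sum of group a
    r <- rank(c(a, b))
    na <- length(a)
    wobs <- sum(r[seq_len(na)])
    assign <- utils::combn(length(r), na)
    wdist <- colSums(matrix(r[assign], nrow = na))
    tol <- 1e-8
    p <- min(1, 2 * min(mean(wdist <= wobs + tol),
                        mean(wdist >= wobs - tol)))
    usedMethod <- "exact"
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE,
                         alternative = "two.sided"))
    p <- min(1, wt$p.value)
    if (exact) usedMethod <- "exact"
  }
  da <- stats::median(a); db <- stats::median(b)
  direction <- if (da > db) "first_up" else if (db > da) "second_up" else "none"
  list(p = p, direction = direction, method = usedMethod)
}

#' Classify how summing the Y gametolog changes the inference
#'
#' Compares the X-only and X-plus-Y-summed test outcomes at level `alpha`:
#' `flipped_direction` when both are significant with opposite directions
#' (the KDM6A-style pattern), `lost_significance` when only the X-only test
#' is significant, `gained_significance` when only the summed test is
#' (the PCDH11X-style pattern), `unchanged` otherwise. Exactly one outcome
#' is returned for every input.
#'
#' @param pXOnly,dirXOnly p-value and direction of the X-only comparison
#' @param pSummed,dirSummed p-value and direction of the summed comparison
#' @param alpha significance level (default 0.05, unadjusted per pair)
#' @return one of `"unchanged"`, `"lost_significance"`,
#'   `"gained_significance"`, `"flipped_direction"`
#' @export
classifyGametologOutcome <- function(pXOnly, dirXOnly, pSummed, dirSummed,
                                     alpha = 0.05) {
  stopifnot(pXOnly >= 0, pXOnly <= 1, pSummed >= 0, pSummed <= 1)
  sigX <- pXOnly <= alpha && dirXOnly != "none"
  sigS <- pSummed <= alpha && dirSummed != "none"
  if (sigX && sigS && dirXOnly != dirSummed) return("flipped_direction")
  if (sigX && !sigS) return("lost_significance")
  if (!sigX && sigS) return("gained_significance")
  "unchanged"
}

#' Per-pair expression series under the two accounting schemes
#'
#' For each X-Y pair present in the CPM matrix, extracts the female X
#' series, the male X series, the male Y series and the male X+Y sum.
#' Female samples are never summed (Y expression observed in females is
#' reported as a diagnostic only). Pairs with a missing gene are skipped
#' with a warning record.
#'
#' @param cpm CPM matrix (genes x samples)
#' @param pairs data.frame with `x_gene`, `y_gene`
#' @param maleSamples,femaleSamples sample-id vectors
#' @return list of per-pair lists (`x_gene`, `y_gene`, `female_x_cpm`,
#'   `male_x_cpm`, `male_y_cpm`, `male_sum_cpm`, `female_y_cpm_max`);
#'   skipped pairs recorded in attribute `skipped`
#' @export
sumGametologExpression <- function(cpm, pairs, maleSamples, femaleSamples) {
  cpm <- as.matrix(cpm)
  stopifnot(all(c(maleSamples, femaleSamples) %in% colnames(cpm)))
  out <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(pairs))) {
    xg <- pairs$x_gene[i]; yg <- pairs$y_gene[i]
    if (!xg %in% rownames(cpm) || !yg %in% rownames(cpm)) {
      warning("pair ", xg, "/", yg, " not fully present; skipped")
      skipped <- c(skipped, xg)
      next
    }
    maleX <- cpm[xg, maleSamples]
    maleY <- cpm[yg, maleSamples]
    out[[length(out) + 1L]] <- list(
      x_gene = xg, y_gene = yg,
      female_x_cpm = cpm[xg, femaleSamples],
      male_x_cpm = maleX, male_y_cpm = maleY,
      male_sum_cpm = maleX + maleY,
      female_y_cpm_max = max(cpm[yg, femaleSamples]))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Run the full gametolog X vs X+Y analysis
#'
#' CPM values (prior-free, on TMM-effective library sizes) are computed from
#' the counts; pairs are retained when the expression rule holds — FPKM
#' above `fpkmThreshold` in every sample of at least one sex for the X
#' member, or the male X+Y summed series passing the same rule — and for
#' each retained pair the female X series is tested against (i) the male X
#' series and (ii) the male X+Y summed series. Outcomes are classified with
#' [classifyGametologOutcome()]; per-pair p-values are unadjusted (a
#' BH-across-pairs column is provided for reference but does not drive the
#' outcome).
#'
#' @param x a [SexCountSet-class] with `sex` in `female`/`male`
#' @param pairs data.frame with `x_gene`, `y_gene` (default the packaged
#'   registry, [gametologPairs()])
#' @param alpha per-pair significance level (default 0.05)
#' @param fpkmThreshold expression-filter threshold (default 1)
#' @param test `"wilcoxon"` (default) or `"ttest"` (Welch) for sensitivity
#'   comparison
#' @param testMethod rank-sum method passed to [rankSumTest()]
#' @return data.frame with one row per retained pair: summary CPMs, both
#'   p-values and directions, BH-adjusted p-values, `outcome`, and the
#'   female Y-expression diagnostic; zero retained pairs yields an empty
#'   table with a message
#' @export
runGametologAnalysis <- function(x, pairs = gametologPairs(), alpha = 0.05,
                                 fpkmThreshold = 1,
                                 test = c("wilcoxon", "ttest"),
                                 testMethod = "auto") {
  stopifnot(is(x, "SexCountSet"))
  test <- match.arg(test)
  if (!nrow(pairs)) stop("pairs list is empty")
  sex <- sampleSex(x)
  females <- names(sex)[sex == "female"]
  males <- names(sex)[sex == "male"]
  if (length(females) < 2 || length(males) < 2)
    stop("need at least 2 samples per sex")
  tmm <- tmmNormalize(x)
  cnt <- countsMatrix(x)
  eff <- tmm$effective_lib_size
  cpm <- computeCPM(cnt, priorCount = 0, libSizes = eff)
  fpkm <- computeFPKM(cnt, lengths = geneLengths(x), libSizes = eff)
  series <- sumGametologExpression(cpm, pairs, males, females)
  passesRule <- function(vF, vM) {
    all(vF > fpkmThreshold) || all(vM > fpkmThreshold)
  }
  rows <- list()
  for (s in series) {
    lenX <- geneLengths(x)[s$x_gene]
    ## male summed series expressed in FPKM units of the X member
    sumFpkm <- s$male_sum_cpm / (lenX / 1e3)
    exprX <- passesRule(fpkm[s$x_gene, females], fpkm[s$x_gene, males])
    exprSum <- passesRule(fpkm[s$x_gene, females], sumFpkm)
    if (!exprX && !exprSum) next
    if (test == "wilcoxon") {
      tX <- rankSumTest(s$female_x_cpm, s$male_x_cpm, method = testMethod)
      tS <- rankSumTest(s$female_x_cpm, s$male_sum_cpm, method = testMethod)
      pX <- tX$p; pS <- tS$p
      dX <- tX$direction; dS <- tS$direction
    } else {
      wx <- stats::t.test(s$female_x_cpm, s$male_x_cpm)
      ws <- stats::t.test(s$female_x_cpm, s$male_sum_cpm)
      pX <- wx$p.value; pS <- ws$p.value
      mX <- mean(s$female_x_cpm) - mean(s$male_x_cpm)
      mS <- mean(s$female_x_cpm) - mean(s$male_sum_cpm)
      dX <- if (mX > 0) "first_up" else if (mX < 0) "second_up" else "none"
      dS <- if (mS > 0) "first_up" else if (mS < 0) "second_up" else "none"
    }
    toDir <- function(d) switch(d, first_up = "female_up",
                                second_up = "male_up", "none")
    rows[[length(rows) + 1L]] <- data.frame(
      x_gene = s$x_gene, y_gene = s$y_gene,
      n_female = length(females), n_male = length(males),
      mean_female_x_cpm = mean(s$female_x_cpm),
      mean_male_x_cpm = mean(s$male_x_cpm),
      mean_male_y_cpm = mean(s$male_y_cpm),
      mean_male_sum_cpm = mean(s$male_sum_cpm),
      p_x_only = pX, direction_x_only = toDir(dX),
      p_summed = pS, direction_summed = toDir(dS),
      female_y_cpm_max = s$female_y_cpm_max,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    message("no gametolog pair passed the expression filter")
    return(data.frame())
  }
  tab <- do.call(rbind, rows)
  tab$adj_p_x_only <- bhAdjust(tab$p_x_only)
  tab$adj_p_summed <- bhAdjust(tab$p_summed)
  tab$outcome <- mapply(function(pX, dX, pS, dS)
    classifyGametologOutcome(pX, dX, pS, dS, alpha),
    tab$p_x_only, tab$direction_x_only, tab$p_summed, tab$direction_summed)
  tab
}
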