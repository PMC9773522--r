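## Independent brute-force oracles and small fixture builders used across the
## suite. Oracles deliberately use naive, loop-based code so they share no
## implementation with the package.

## tiny SexCountSet with explicit counts and sexes
makeCountSet <- function(counts, sex = NULL, lengths = NULL, classes = NULL,
                         replicate_group = NULL, batch = NULL) {
  counts <- as.matrix(counts)
  sm <- data.frame(row.names = colnames(counts))
  if (!is.null(sex)) sm$sex <- sex
  if (!is.null(replicate_group)) sm$replicate_group <- replicate_group
  if (!is.null(batch)) sm$batch <- batch
  ga <- data.frame(row.names = rownames(counts))
  if (!is.null(lengths)) ga$length_bp <- lengths
  if (!is.null(classes)) ga$chrom_class <- classes
  SexCountSet(counts,
              geneAnnotation = if (ncol(ga)) ga else NULL,
              sampleMetadata = if (ncol(sm)) sm else NULL)
}

## brute-force TMM: doubly trimmed, delta-method-weighted mean of M-values,
## computed gene by gene with explicit rank bookkeeping
tmmOracle <- function(counts, logratioTrim = 0.30, absTrim = 0.05) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  uq <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts)))
    uq[j] <- unname(quantile(counts[, j] / lib[j], 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    M <- A <- W <- numeric(0)
    for (g in seq_len(nrow(counts))) {
      o <- counts[g, j]; r <- counts[g, ref]
      if (o > 0 && r > 0) {
        po <- o / lib[j]; pr <- r / lib[ref]
        M <- c(M, log2(po / pr))
        A <- c(A, (log2(po) + log2(pr)) / 2)
        W <- c(W, (lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r))
      }
    }
    if (!length(M) || max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * absTrim) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    num <- den <- 0
    for (g in seq_len(n)) {
      if (rM[g] >= loM && rM[g] <= hiM && rA[g] >= loA && rA[g] <= hiA) {
        num <- num + M[g] / W[g]
        den <- den + 1 / W[g]
      }
    }
    f[j] <- if (den > 0 && is.finite(num / den)) 2^(num / den) else 1
  }
  f / exp(mean(log(f)))
}

## exact two-sided rank-sum p by full enumeration of group assignments
wilcoxEnumOracle <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  wobs <- sum(r[seq_len(na)])
  assign <- combn(length(pooled), na)
  wdist <- apply(assign, 2, function(idx) sum(r[idx]))
  tol <- 1e-8
  min(1, 2 * min(mean(wdist <= wobs + tol), mean(wdist >= wobs - tol)))
}

## Benjamini-Hochberg step-up computed by the textbook recursion
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  pmin(q, 1)
}

## toy two-record genome with a 100 bp Y chromosome
toyGenome <- function() {
  set.seed(42)
  mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                          collapse = "")
  Biostrings::DNAStringSet(c(chr1 = mk(150), chrY = mk(100)))
}
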