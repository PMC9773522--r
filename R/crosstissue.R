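## Cross-tissue comparison: log2 female-to-male expression ratios per tissue
## and gene-class-stratified Pearson correlation of placenta ratios with each
## adult tissue's ratios, BH-corrected per class column.

GENE_CLASS_SETS <- c("all", "exclude_sd", "all_sd", "autosomal_sd",
                     "x_linked_sd", "y_linked_sd")

#' Log2 female-to-male expression ratios
#'
#' `ratio = log2((F + eps) / (M + eps))` per gene and tissue, where `eps`
#' avoids infinite ratios for genes expressed in one sex only (e.g.
#' Y-linked genes with zero female TPM) while preserving the sign of the
#' bias. Genes with zero mean TPM in both sexes are dropped and recorded in
#' the `dropped` attribute.
#'
#' @param meanTpm data.frame with columns `tissue` (optional; a single
#'   tissue assumed when absent), `gene`, `mean_tpm_female`,
#'   `mean_tpm_male`
#' @param epsilon pseudo-TPM added to both means (default 0.01)
#' @return the input with a `log2_fm_ratio` column, both-zero genes
#'   removed; attribute `dropped` lists them per tissue
#' @export
computeFMRatios <- function(meanTpm, epsilon = 0.01) {
  meanTpm <- as.data.frame(meanTpm)
  need <- c("gene", "mean_tpm_female", "mean_tpm_male")
  stopifnot(all(need %in% colnames(meanTpm)))
  if (!"tissue" %in% colnames(meanTpm)) meanTpm$tissue <- "tissue"
  if (any(meanTpm$mean_tpm_female < 0) || any(meanTpm$mean_tpm_male < 0))
    stop("mean TPM values must be non-negative")
  if (epsilon <= 0) stop("epsilon must be positive")
  zero <- meanTpm$mean_tpm_female == 0 & meanTpm$mean_tpm_male == 0
  dropped <- meanTpm[zero, c("tissue", "gene"), drop = FALSE]
  out <- meanTpm[!zero, , drop = FALSE]
  out$log2_fm_ratio <- log2((out$mean_tpm_female + epsilon) /
                            (out$mean_tpm_male + epsilon))
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Partition genes into the class sets used for ratio correlation
#'
#' `all` is the supplied universe (genes expressed in the placenta with
#' ratio data in every compared tissue); `all_sd` is the union of
#' significant genes over the provided differential-expression tables
#' (e.g. term and late-first-trimester) intersected with `all`;
#' `autosomal_sd` (autosomes and mitochondrial genes grouped together),
#' `x_linked_sd` (X and X-PAR) and `y_linked_sd` split `all_sd` by
#' chromosome class; `exclude_sd = all \\ all_sd`.
#'
#' @param deTables a [deTable()] result or list of them
#' @param annotation data.frame keyed by gene with `chrom_class`
#' @param expressedGenes character vector, the `all` universe
#' @return named list of gene-id vectors (classes in
#'   `all`, `exclude_sd`, `all_sd`, `autosomal_sd`, `x_linked_sd`,
#'   `y_linked_sd`)
#' @export
partitionGeneClasses <- function(deTables, annotation, expressedGenes) {
  if (is.data.frame(deTables)) deTables <- list(deTables)
  sig <- unique(unlist(lapply(deTables, function(t)
    t$gene[t$significant]), use.names = FALSE))
  all <- unique(expressedGenes)
  allSd <- intersect(sig, all)
  anno <- as.data.frame(annotation)
  key <- if ("gene" %in% colnames(anno)) anno$gene else rownames(anno)
  cls <- as.character(anno$chrom_class[match(allSd, key)])
  list(all = all,
       exclude_sd = setdiff(all, allSd),
       all_sd = allSd,
       autosomal_sd = allSd[cls %in% c("autosome", "mito")],
       x_linked_sd = allSd[cls %in% c("X", "X_PAR")],
       y_linked_sd = allSd[cls %in% "Y"])
}

#' Correlate placenta ratios with each tissue's ratios by gene class
#'
#' For every tissue and every gene-class set, the Pearson correlation of the
#' log2 female-to-male ratios over the genes shared (with finite ratios)
#' between the placenta table and that tissue. P-values come from the
#' t-transform of r; BH adjustment is applied within each gene-class column
#' across tissues. Cells with fewer than 3 shared genes are reported as not
#' computed.
#'
#' @param placentaRatios single-tissue ratio table from [computeFMRatios()]
#' @param panelRatios multi-tissue ratio table from [computeFMRatios()]
#' @param classes gene-class sets from [partitionGeneClasses()]
#' @param adjust multiple-testing family; `"bh"` per class column (default)
#'   or `"bh_global"` across all cells
#' @param method `"pearson"` (default) or `"spearman"`
#' @param alpha significance level on the adjusted p (default 0.05)
#' @return data.frame with one row per tissue x class:
#'   `tissue`, `gene_class`, `n_genes`, `r`, `p`, `adj_p`, `significant`,
#'   `computed`
#' @export
correlateRatios <- function(placentaRatios, panelRatios, classes,
                            adjust = c("bh", "bh_global"),
                            method = c("pearson", "spearman"),
                            alpha = 0.05) {
  adjust <- match.arg(adjust)
  method <- match.arg(method)
  stopifnot(all(GENE_CLASS_SETS %in% names(classes)))
  pr <- stats::setNames(placentaRatios$log2_fm_ratio, placentaRatios$gene)
  pr <- pr[is.finite(pr)]
  tissues <- unique(panelRatios$tissue)
  rows <- list()
  anyShared <- FALSE
  for (tis in tissues) {
    sub <- panelRatios[panelRatios$tissue == tis, , drop = FALSE]
    tr <- stats::setNames(sub$log2_fm_ratio, sub$gene)
    tr <- tr[is.finite(tr)]
    shared <- intersect(names(pr), names(tr))
    for (cl in GENE_CLASS_SETS) {
      genes <- intersect(classes[[cl]], shared)
      n <- length(genes)
      if (n >= 3 && stats::sd(pr[genes]) > 0 && stats::sd(tr[genes]) > 0) {
        ct <- stats::cor.test(pr[genes], tr[genes], method = method,
                              exact = FALSE)
        r <- unname(ct$estimate); p <- ct$p.value
        computed <- TRUE
        anyShared <- TRUE
      } else {
        r <- NA_real_; p <- NA_real_; computed <- FALSE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = tis, gene_class = cl, n_genes = n, r = r, p = p,
        computed = computed, stringsAsFactors = FALSE)
    }
  }
  if (!anyShared) stop("no shared genes between placenta and panel")
  out <- do.call(rbind, rows)
  out$adj_p <- NA_real_
  ok <- !is.na(out$p)
  if (adjust == "bh") {
    for (cl in GENE_CLASS_SETS) {
      sel <- ok & out$gene_class == cl
      if (any(sel)) out$adj_p[sel] <- bhAdjust(out$p[sel])
    }
  } else {
    out$adj_p[ok] <- bhAdjust(out$p[ok])
  }
  out$significant <- !is.na(out$adj_p) & out$adj_p <= alpha
  out
}
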