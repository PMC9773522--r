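## Synthetic-data generator: negative-binomial counts with known ground truth
## emulating a two-sex placental RNA-seq study (marker genes, Y-linked
## male-only genes, X-inactivation escapers, gametolog pairs, batches,
## technical replicates) plus QC profiles and a multi-tissue TPM panel.

Y_MARKERS <- c("EIF1AY", "KDM5D", "UTY", "DDX3Y", "RPS4Y1")
XIST_MARKER <- "XIST"

## marker-gene CPM targets: unambiguous sex-complement signal
XIST_CPM_FEMALE <- 100
XIST_CPM_MALE <- 0.1
YMARKER_CPM_MALE <- 20

## fixed sample layout (ids, sex, batch, replicate groups); no RNG used so it
## can be shared between count and QC simulation
.sampleLayout <- function(design) {
  bio <- data.frame(
    bio_id = c(sprintf("F%02d", seq_len(design@nFemale)),
               sprintf("M%02d", seq_len(design@nMale))),
    sex = rep(c("female", "male"), c(design@nFemale, design@nMale)),
    stringsAsFactors = FALSE)
  ## interleaved batch assignment keeps batches balanced by sex
  bio$batch <- paste0("batch", rep_len(seq_len(design@nBatches), nrow(bio)))
  reps <- design@replicateCountPerSample
  samp <- bio[rep(seq_len(nrow(bio)), each = reps), , drop = FALSE]
  samp$replicate <- rep(seq_len(reps), nrow(bio))
  samp$sample_id <- if (reps > 1) {
    paste0(samp$bio_id, "_r", samp$replicate)
  } else samp$bio_id
  rownames(samp) <- samp$sample_id
  samp
}

## male X/Y expected CPM for a planted gametolog pair; female X CPM is f
.gametologMaleCpm <- function(f, yfrac, outcome, effect) {
  maleX <- switch(outcome,
    unchanged = f / 2^effect,   # clear female bias, X-only and summed
    lost = f / (1 + yfrac),     # summed male mean equals female mean
    flipped = 0.6 * f,          # female-biased X, male-biased after summing
    gained = f)                 # no X-only difference; summing adds Y
  c(maleX = maleX, maleY = yfrac * maleX)
}

## gene inventory with expected CPM per sex; draws RNG
.geneInventory <- function(design) {
  eff <- design@effectSizeLog2FC
  blocks <- list()
  addBlock <- function(gene, class, cpmF, cpmM, partner = NA_character_,
                       sexde = NULL) {
    if (!length(gene)) return()
    if (is.null(sexde)) sexde <- abs(log2(cpmF) - log2(cpmM)) > 1e-12
    blocks[[length(blocks) + 1L]] <<- data.frame(
      gene = gene, gene_class = class, cpm_female = cpmF, cpm_male = cpmM,
      gametolog_partner = partner, is_sexde = sexde, stringsAsFactors = FALSE)
  }
  nN <- design@nGenesAutosomalNull
  if (nN) {
    b <- 2^stats::rnorm(nN, 4, 2)
    addBlock(sprintf("AUTO_NULL_%05d", seq_len(nN)), "autosome", b, b,
             sexde = rep(FALSE, nN))
  }
  nS <- design@nGenesAutosomalSexDE
  if (nS) {
    b <- 2^stats::rnorm(nS, 4, 2)
    sgn <- rep_len(c(1, -1), nS)
    addBlock(sprintf("AUTO_SD_%05d", seq_len(nS)), "autosome",
             b * 2^(sgn * eff / 2), b * 2^(-sgn * eff / 2))
  }
  nX <- design@nGenesXEscape
  if (nX) {
    b <- 2^stats::rnorm(nX, 4, 2)
    addBlock(sprintf("XESC_%05d", seq_len(nX)), "X",
             b * 2^(eff / 2), b * 2^(-eff / 2))
  }
  nY <- design@nGenesYLinked
  if (nY) {
    b <- 2^stats::rnorm(nY, 3, 1)
    addBlock(sprintf("YLNK_%05d", seq_len(nY)), "Y", rep(0, nY), b,
             sexde = rep(TRUE, nY))
  }
  addBlock(XIST_MARKER, "X", XIST_CPM_FEMALE, XIST_CPM_MALE)
  addBlock(Y_MARKERS, "Y", rep(0, 5), rep(YMARKER_CPM_MALE, 5),
           sexde = rep(TRUE, 5))
  gp <- design@gametologPairs
  if (nrow(gp)) {
    for (i in seq_len(nrow(gp))) {
      f <- 2^gp$x_base_log2cpm[i]
      m <- .gametologMaleCpm(f, gp$y_fraction_of_x[i], gp$planted_outcome[i],
                             eff)
      addBlock(gp$x_name[i], "X", f, m[["maleX"]], partner = gp$y_name[i])
      addBlock(gp$y_name[i], "Y", 0, m[["maleY"]], partner = gp$x_name[i],
               sexde = TRUE)
    }
  }
  inv <- do.call(rbind, blocks)
  if (anyDuplicated(inv$gene))
    stop("gametologPairs: pair names collide with generated gene names")
  inv$length_bp <- round(exp(stats::runif(nrow(inv), log(500), log(10000))))
  inv
}

.simulateExperimentImpl <- function(design) {
  inv <- .geneInventory(design)
  layout <- .sampleLayout(design)
  nG <- nrow(inv)
  nS <- nrow(layout)

  ## per-gene, per-batch multiplicative offsets (log2-additive), batch1 = 0
  bOff <- matrix(0, nG, design@nBatches)
  if (design@nBatches > 1 && design@batchEffectSd > 0)
    bOff[, -1] <- stats::rnorm(nG * (design@nBatches - 1), 0,
                               design@batchEffectSd)

  ## biological-sample covariates (birth weight by sex per the study means)
  bioIds <- unique(layout$bio_id)
  bioSex <- layout$sex[match(bioIds, layout$bio_id)]
  bw <- ifelse(bioSex == "female", stats::rnorm(length(bioIds), 3.3, 0.4),
               stats::rnorm(length(bioIds), 3.6, 0.4))
  pc1 <- stats::rnorm(length(bioIds))
  pc2 <- stats::rnorm(length(bioIds))
  names(bw) <- names(pc1) <- names(pc2) <- bioIds

  layout$lane <- paste0("lane", sample.int(4, nS, replace = TRUE))
  libs <- round(stats::runif(nS, design@libSizeRange[1],
                             design@libSizeRange[2]))

  cpmSex <- cbind(female = inv$cpm_female, male = inv$cpm_male)
  counts <- matrix(0L, nG, nS,
                   dimnames = list(inv$gene, layout$sample_id))
  for (j in seq_len(nS)) {
    b <- as.integer(sub("batch", "", layout$batch[j]))
    cpm <- cpmSex[, layout$sex[j]] * 2^bOff[, b]
    cpm <- cpm / sum(cpm) * 1e6           # expected CPM sums to one million
    mu <- cpm * libs[j] / 1e6
    counts[, j] <- stats::rnbinom(nG, size = 1 / design@nbDispersion, mu = mu)
  }

  meta <- data.frame(
    sample = layout$sample_id,
    sex = layout$sex,
    batch = layout$batch,
    lane = layout$lane,
    birth_weight_kg = bw[layout$bio_id],
    ancestry_pc1 = pc1[layout$bio_id],
    ancestry_pc2 = pc2[layout$bio_id],
    replicate_group = layout$bio_id,
    lib_size_target = libs,
    stringsAsFactors = FALSE)

  anno <- data.frame(gene = inv$gene, chrom_class = inv$gene_class,
                     length_bp = inv$length_bp,
                     gametolog_partner = inv$gametolog_partner,
                     stringsAsFactors = FALSE)
  truth <- data.frame(
    gene = inv$gene,
    true_log2fc_f_vs_m = log2(inv$cpm_female / inv$cpm_male),
    gene_class = inv$gene_class,
    is_sexde = inv$is_sexde,
    gametolog_partner = inv$gametolog_partner,
    stringsAsFactors = FALSE)

  list(countSet = SexCountSet(counts, geneAnnotation = anno,
                              sampleMetadata = meta),
       truth = truth)
}

#' Simulate a two-sex placental RNA-seq experiment
#'
#' Draws negative-binomial counts for the gene inventory described by the
#' design: autosomal null genes, autosomal sex-DE genes and X-inactivation
#' escapers at the planted effect size, Y-linked genes with zero female
#' counts, the six sex-complement marker genes (XIST at 100 CPM in females /
#' 0.1 in males; the five Y markers at 20 CPM in males / 0 in females), and
#' any planted X-Y gametolog pairs. Batch offsets are additive on the log2
#' scale before sampling; each biological sample contributes
#' `replicateCountPerSample` technical-replicate columns sharing one
#' `replicate_group`. Expected per-sample CPM is rescaled to sum to one
#' million so column sums match the drawn library sizes up to sampling noise.
#' The same seed yields byte-identical output.
#'
#' @param design a [SimulationDesign-class] from [simulationDesign()]
#' @return list with `countSet` (a [SexCountSet-class]) and `truth`, a
#'   data.frame with per-gene `true_log2fc_f_vs_m` (`-Inf` for male-only
#'   genes), `gene_class`, `is_sexde` and `gametolog_partner`.
#' @export
simulateExperiment <- function(design) {
  stopifnot(is(design, "SimulationDesign"))
  methods::validObject(design)
  withr::with_seed(design@seed, .simulateExperimentImpl(design))
}

QC_FAIL_MODES <- c("low_reads", "high_reads", "gc_fail", "sex_mismatch", "pass")

#' Simulate per-sample QC summaries
#'
#' Emits one record per RNA-seq sample with post-trimming read counts drawn
#' around 35 M reads (the scale of the emulated study), a per-sequence GC
#' deviation fraction, and the reported sex. `failSpec` plants violations of
#' exactly one rule per named sample: `low_reads` (< 12.5 M), `high_reads`
#' (> 90 M), `gc_fail` (deviation fraction > 0.30) or `sex_mismatch`
#' (reported sex flipped relative to the true complement).
#'
#' @param design a [SimulationDesign-class]
#' @param failSpec data.frame with columns `sample` and `mode`, or NULL
#' @return data.frame with columns `sample`, `reads_post_trim`,
#'   `gc_deviation_fraction`, `reported_sex`, `replicate_group`
#' @export
simulateQCProfiles <- function(design, failSpec = NULL) {
  stopifnot(is(design, "SimulationDesign"))
  methods::validObject(design)
  layout <- .sampleLayout(design)
  qc <- withr::with_seed(design@seed + 1000L, {
    n <- nrow(layout)
    reads <- round(pmin(pmax(stats::rnorm(n, 35e6, 8e6), 13e6), 85e6))
    gc <- stats::runif(n, 0, 0.10)
    data.frame(sample = layout$sample_id,
               reads_post_trim = reads,
               gc_deviation_fraction = gc,
               reported_sex = layout$sex,
               replicate_group = layout$bio_id,
               stringsAsFactors = FALSE)
  })
  if (!is.null(failSpec) && nrow(failSpec)) {
    if (!all(c("sample", "mode") %in% colnames(failSpec)))
      stop("failSpec needs columns 'sample' and 'mode'")
    bad <- setdiff(failSpec$sample, qc$sample)
    if (length(bad)) stop("unknown sample(s) in failSpec: ",
                          paste(bad, collapse = ", "))
    badm <- setdiff(failSpec$mode, QC_FAIL_MODES)
    if (length(badm)) stop("unknown failure mode(s): ",
                           paste(badm, collapse = ", "))
    qc <- withr::with_seed(design@seed + 2000L, {
      for (i in seq_len(nrow(failSpec))) {
        j <- match(failSpec$sample[i], qc$sample)
        qc[j, ] <- switch(failSpec$mode[i],
          low_reads = { qc$reads_post_trim[j] <-
                          round(stats::runif(1, 5e6, 12.4e6)); qc[j, ] },
          high_reads = { qc$reads_post_trim[j] <-
                           round(stats::runif(1, 9.1e7, 1.2e8)); qc[j, ] },
          gc_fail = { qc$gc_deviation_fraction[j] <-
                        stats::runif(1, 0.31, 0.50); qc[j, ] },
          sex_mismatch = { qc$reported_sex[j] <-
                             ifelse(qc$reported_sex[j] == "female",
                                    "male", "female"); qc[j, ] },
          pass = qc[j, ])
      }
      qc
    })
  }
  qc
}

#' Simulate a multi-tissue mean-TPM-by-sex panel
#'
#' Builds a long table of per-tissue, per-gene mean TPM for each sex, anchored
#' on the ground-truth female/male ratios of a simulated experiment. The first
#' tissue, named `"placenta"`, carries the base ratios; sex-linked genes (X,
#' X_PAR, Y) keep the base ratio in every tissue when `sharedSexLinked` is
#' TRUE, while autosomal sex-DE effects are re-drawn per tissue from
#' N(0, `autosomalTissueSd`) — tissue-specific autosomal effects centred on no
#' effect. Log-normal measurement noise of `noiseSd` (log2 sd) is applied to
#' every mean; zero means (Y-linked genes in females) stay exactly zero.
#'
#' @param truth truth table from [simulateExperiment()]
#' @param nTissues number of adult tissues (>= 2), named `tissue_01`, ...
#' @param sharedSexLinked keep sex-linked ratios identical across tissues
#' @param autosomalTissueSd sd (log2 units) of per-tissue autosomal effects
#' @param seed RNG seed
#' @param noiseSd log2-scale sd of multiplicative measurement noise
#' @return data.frame with columns `tissue`, `gene`, `mean_tpm_female`,
#'   `mean_tpm_male`
#' @export
simulateTissuePanel <- function(truth, nTissues = 5, sharedSexLinked = TRUE,
                                autosomalTissueSd = 0.5, seed = 1,
                                noiseSd = 0.05) {
  if (nTissues < 2) stop("nTissues must be >= 2")
  if (autosomalTissueSd < 0) stop("autosomalTissueSd must be >= 0")
  stopifnot(all(c("gene", "true_log2fc_f_vs_m", "gene_class", "is_sexde") %in%
                colnames(truth)))
  withr::with_seed(as.integer(seed), {
    n <- nrow(truth)
    base <- 2^stats::rnorm(n, 4, 2)
    lfc0 <- truth$true_log2fc_f_vs_m
    sexlinked <- truth$gene_class %in% c("X", "Y", "X_PAR")
    autoSD <- !sexlinked & truth$is_sexde
    mk <- function(lfc) {
      f <- ifelse(lfc == -Inf, 0, base * 2^(pmin(lfc, 50) / 2))
      m <- ifelse(lfc == Inf, 0, base * 2^(-pmax(lfc, -50) / 2))
      list(f = f, m = m)
    }
    noisy <- function(v) v * 2^stats::rnorm(n, 0, noiseSd)
    tissues <- c("placenta", sprintf("tissue_%02d", seq_len(nTissues)))
    out <- vector("list", length(tissues))
    for (t in seq_along(tissues)) {
      lfc <- lfc0
      if (t > 1) {
        if (!sharedSexLinked)
          lfc[sexlinked] <- stats::rnorm(sum(sexlinked), 0, autosomalTissueSd)
        lfc[autoSD] <- stats::rnorm(sum(autoSD), 0, autosomalTissueSd)
      }
      e <- mk(lfc)
      out[[t]] <- data.frame(tissue = tissues[t], gene = truth$gene,
                             mean_tpm_female = noisy(e$f),
                             mean_tpm_male = noisy(e$m),
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Write a simulated experiment to plain-text files
#'
#' Writes the count matrix (genes x samples TSV with a header row of sample
#' ids), the sample metadata, the gene annotation and the truth table.
#'
#' @param sim result of [simulateExperiment()]
#' @param outdir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeSimulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cs <- sim$countSet
  paths <- file.path(outdir, c("counts.tsv", "sample_metadata.tsv",
                               "gene_annotation.tsv", "truth.tsv"))
  utils::write.table(data.frame(gene = rownames(cs), countsMatrix(cs),
                                check.names = FALSE),
                     paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(SummarizedExperiment::colData(cs)),
                     paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(SummarizedExperiment::rowData(cs)),
                     paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
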