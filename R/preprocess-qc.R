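## Sample-level QC: sex-chromosome-complement inference from marker genes,
## exclusion rules (read-count window, GC deviation, sex mismatch), and
## complement-specific hard masking of reference FASTA sequences.

SEX_MARKERS <- c(Y_MARKERS, XIST_MARKER)

#' Infer sex chromosome complement from marker-gene expression
#'
#' A sample carrying a Y chromosome expresses most or all of the five
#' Y-linked markers (EIF1AY, KDM5D, UTY, DDX3Y, RPS4Y1); a sample with at
#' least two X chromosomes expresses XIST. The decision rule: `XY_like` if at
#' least 4 of the 5 Y markers exceed `yCpmThreshold`; `XX_like` if at most 1
#' Y marker exceeds it and XIST exceeds `xistCpmThreshold`; otherwise
#' `ambiguous` (for instance when all six markers are silent).
#'
#' @param markerCpm CPM matrix (genes x samples) containing rows for all six
#'   marker genes, or a [SexCountSet-class] (CPM computed from raw counts)
#' @param yCpmThreshold CPM above which a Y marker counts as expressed
#' @param xistCpmThreshold CPM above which XIST counts as expressed
#' @return data.frame with one row per sample: `sample`, `call`
#'   (`XX_like`/`XY_like`/`ambiguous`), `y_markers_expressed` (0-5),
#'   `xist_cpm`, and one `cpm_<marker>` evidence column per marker
#' @examples
#' cpm <- matrix(c(150, rep(0.2, 5), 0.3, rep(8, 5)), nrow = 6,
#'               dimnames = list(c("XIST", "EIF1AY", "KDM5D", "UTY", "DDX3Y",
#'                                 "RPS4Y1"), c("s1", "s2")))
#' inferSexComplement(cpm)
#' @export
inferSexComplement <- function(markerCpm, yCpmThreshold = 1,
                               xistCpmThreshold = 10) {
  if (yCpmThreshold <= 0 || xistCpmThreshold <= 0)
    stop("thresholds must be > 0")
  if (is(markerCpm, "SexCountSet")) markerCpm <- computeCPM(markerCpm)
  markerCpm <- as.matrix(markerCpm)
  miss <- setdiff(SEX_MARKERS, rownames(markerCpm))
  if (length(miss))
    stop("marker gene(s) missing from matrix: ", paste(miss, collapse = ", "))
  samples <- colnames(markerCpm)
  ycpm <- markerCpm[Y_MARKERS, , drop = FALSE]
  xist <- markerCpm[XIST_MARKER, ]
  nY <- colSums(ycpm > yCpmThreshold)
  call <- ifelse(nY >= 4, "XY_like",
          ifelse(nY <= 1 & xist > xistCpmThreshold, "XX_like", "ambiguous"))
  evidence <- t(ycpm)
  colnames(evidence) <- paste0("cpm_", Y_MARKERS)
  out <- data.frame(sample = samples, call = call,
                    y_markers_expressed = as.integer(nY), xist_cpm = xist,
                    evidence, row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Apply sample exclusion rules
#'
#' A sample is excluded when its post-trimming read count falls outside
#' `[minReads, maxReads]`, when its per-sequence GC deviation fraction
#' exceeds `maxGcFraction`, or when its inferred sex complement disagrees
#' with the reported sex (an `ambiguous` call counts as a mismatch whenever a
#' sex was reported). Reasons are exhaustive: a sample violating several
#' rules is listed once per rule. When `records` carries a
#' `replicate_group`, excluding any technical replicate removes the whole
#' biological sample (reason `replicate_excluded` for the dragged-along
#' members).
#'
#' @param records data.frame with `sample`, `reads_post_trim`,
#'   `gc_deviation_fraction`, `reported_sex` and optionally `replicate_group`
#' @param calls data.frame from [inferSexComplement()] covering every record
#' @param minReads,maxReads post-trimming read-count window (defaults
#'   12.5 M and 90 M)
#' @param maxGcFraction maximum tolerated GC deviation fraction (default 0.30)
#' @return list with `kept` (character vector of retained sample ids, input
#'   order) and `exclusions` (data.frame `sample`, `reason`, one row per
#'   sample-reason)
#' @export
applyQCFilters <- function(records, calls, minReads = 12.5e6,
                           maxReads = 90e6, maxGcFraction = 0.30) {
  stopifnot(all(c("sample", "reads_post_trim", "gc_deviation_fraction",
                  "reported_sex") %in% colnames(records)))
  if (any(records$gc_deviation_fraction < 0 |
          records$gc_deviation_fraction > 1))
    stop("gc_deviation_fraction must lie in [0, 1]")
  miss <- setdiff(records$sample, calls$sample)
  if (length(miss))
    stop("no sex-complement call for sample(s): ",
         paste(miss, collapse = ", "))
  call <- calls$call[match(records$sample, calls$sample)]
  reasons <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- character(0)
    if (records$reads_post_trim[i] < minReads) r <- c(r, "low_reads")
    if (records$reads_post_trim[i] > maxReads) r <- c(r, "high_reads")
    if (records$gc_deviation_fraction[i] > maxGcFraction)
      r <- c(r, "gc_content")
    rep_sex <- records$reported_sex[i]
    if (rep_sex %in% c("female", "male")) {
      expected <- ifelse(rep_sex == "female", "XX_like", "XY_like")
      if (call[i] != expected) r <- c(r, "sex_mismatch")
    }
    reasons[[i]] <- r
  }
  excluded <- lengths(reasons) > 0
  if ("replicate_group" %in% colnames(records)) {
    badGroups <- unique(records$replicate_group[excluded])
    dragged <- records$replicate_group %in% badGroups & !excluded
    reasons[dragged] <- list("replicate_excluded")
    excluded <- excluded | dragged
  }
  exclusions <- data.frame(
    sample = rep(records$sample, lengths(reasons)),
    reason = unlist(reasons, use.names = FALSE),
    stringsAsFactors = FALSE)
  list(kept = records$sample[!excluded], exclusions = exclusions)
}

#' Read pseudoautosomal-region intervals from a BED file
#'
#' BED intervals are 0-based half-open on disk; they are converted to the
#' 1-based inclusive coordinates used by [maskReference()].
#'
#' @param path BED file with at least chrom/start/end columns
#' @return data.frame with `chromosome`, `start`, `end` (1-based inclusive)
#' @export
readParBed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED file needs at least 3 columns")
  data.frame(chromosome = as.character(bed[[1]]),
             start = as.integer(bed[[2]]) + 1L,
             end = as.integer(bed[[3]]),
             stringsAsFactors = FALSE)
}

#' Hard-mask a reference genome for a sex chromosome complement
#'
#' For samples without a Y chromosome the entire Y record is replaced with
#' `N` (`mode = "whole_y"`), so homologous X-Y reads cannot mis-map to Y; for
#' samples with a Y the pseudoautosomal regions of Y are masked
#' (`mode = "y_pars"`) because they are duplicated verbatim on X. Sequence
#' lengths are never changed, bases outside the target regions (including
#' soft-masked lowercase) are preserved byte-for-byte, and masking is
#' idempotent.
#'
#' @param seqs a [Biostrings::XStringSet] (`DNAStringSet` or `BStringSet`)
#'   or path to a FASTA file (names are truncated at the first whitespace);
#'   files are read as `BStringSet` so soft-masked lowercase survives
#'   untouched
#' @param mode `"whole_y"` or `"y_pars"`
#' @param yChromName name of the Y record (required for `whole_y`)
#' @param parIntervals data.frame of 1-based inclusive intervals
#'   (`chromosome`, `start`, `end`), e.g. from [readParBed()]; used in
#'   `y_pars` mode
#' @return list with `sequences` (masked `BStringSet`, case preserved
#'   outside the masked regions) and `report`
#'   (data.frame `record`, `length`, `masked_bases` giving the size of the
#'   masked region per record)
#' @export
maskReference <- function(seqs, mode = c("whole_y", "y_pars"),
                          yChromName = "chrY", parIntervals = NULL) {
  mode <- match.arg(mode)
  if (is.character(seqs) && length(seqs) == 1) {
    seqs <- Biostrings::readBStringSet(seqs)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  }
  stopifnot(is(seqs, "XStringSet"))
  chars <- as.character(seqs)
  lens <- nchar(chars)
  masked <- stats::setNames(rep(0, length(chars)), names(chars))
  if (mode == "whole_y") {
    if (!yChromName %in% names(chars))
      stop("Y record '", yChromName, "' not found in reference")
    chars[yChromName] <- strrep("N", lens[yChromName])
    masked[yChromName] <- lens[yChromName]
  } else {
    if (!is.null(parIntervals) && nrow(parIntervals)) {
      stopifnot(all(c("chromosome", "start", "end") %in%
                    colnames(parIntervals)))
      for (i in seq_len(nrow(parIntervals))) {
        chrom <- parIntervals$chromosome[i]
        s <- parIntervals$start[i]; e <- parIntervals$end[i]
        if (!chrom %in% names(chars))
          stop("interval chromosome '", chrom, "' not in reference")
        if (s < 1 || e > lens[chrom] || s > e)
          stop("interval [", s, ", ", e, "] outside bounds of '", chrom, "'")
        substr(chars[chrom], s, e) <- strrep("N", e - s + 1)
        masked[chrom] <- masked[chrom] + (e - s + 1)
      }
    }
  }
  out <- Biostrings::BStringSet(chars)
  names(out) <- names(chars)
  list(sequences = out,
       report = data.frame(record = names(chars), length = as.integer(lens),
                           masked_bases = as.integer(masked),
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' Mask a reference FASTA file on disk
#'
#' Convenience wrapper around [maskReference()] that reads `fastaIn`, masks,
#' and writes `fastaOut` with a fixed line width.
#'
#' @inheritParams maskReference
#' @param fastaIn,fastaOut input and output FASTA paths
#' @param lineWidth bases per output FASTA line
#' @return the masking report, invisibly
#' @export
maskReferenceFile <- function(fastaIn, fastaOut, mode = c("whole_y", "y_pars"),
                              yChromName = "chrY", parIntervals = NULL,
                              lineWidth = 60) {
  res <- maskReference(fastaIn, mode = mode, yChromName = yChromName,
                       parIntervals = parIntervals)
  Biostrings::writeXStringSet(res$sequences, fastaOut, width = lineWidth)
  invisible(res$report)
}
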