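#' Library QC summary: retention and mapped rates
#'
#' Per-library read accounting as reported in RNA-seq QC tables:
#' `retention_rate = 100 * clean / raw` and
#' `mapped_rate = 100 * mapped / clean`, both rounded half-up to two
#' decimals. Vectorized over libraries.
#'
#' @param raw,clean,mapped Non-negative integer read counts with
#'   `mapped <= clean <= raw` and `raw, clean > 0`.
#' @param sample_id Optional library identifiers.
#' @return A data.frame with the read counts and the two rates (percent,
#'   2 decimals).
#' @examples
#' summarizeLibraryQC(13871140, 13443019, 11622834)
#' @export
summarizeLibraryQC <- function(raw, clean, mapped, sample_id = NULL) {
  n <- length(raw)
  if (length(clean) != n || length(mapped) != n) {
    stop("'raw', 'clean' and 'mapped' must have equal length")
  }
  if (any(is.na(raw) | is.na(clean) | is.na(mapped))) {
    stop("read counts must not be missing")
  }
  if (any(raw <= 0) || any(clean <= 0)) {
    stop("zero raw or clean reads: rates are undefined")
  }
  if (any(mapped < 0) || any(mapped > clean) || any(clean > raw)) {
    stop("require 0 <= mapped <= clean <= raw")
  }
  if (is.null(sample_id)) sample_id <- paste0("sample", seq_len(n))
  data.frame(sample_id = sample_id,
             raw_reads = raw, clean_reads = clean, mapped_reads = mapped,
             retention_rate = roundHalfUp(100 * clean / raw, 2),
             mapped_rate = roundHalfUp(100 * mapped / clean, 2),
             stringsAsFactors = FALSE)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the reference for each gene is the
#' geometric mean of its counts across samples, restricted to genes with
#' strictly positive counts in every sample; a sample's factor is the
#' median over those genes of count / reference.
#'
#' @param counts Non-negative count matrix (genes x samples, >= 2
#'   samples), or a [TripletCountSet-class].
#' @return Positive numeric vector of size factors, one per sample.
#' @examples
#' m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
#' sizeFactorsMedianRatios(m)
#' @export
sizeFactorsMedianRatios <- function(counts) {
  if (is(counts, "TripletCountSet")) counts <- counts(counts)
  .assertCountMatrix(counts)
  if (ncol(counts) < 2L) stop("need at least two samples")
  allPos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allPos)) {
    stop("no gene has positive counts in every sample; a pseudo-reference ",
         "fallback is not applied silently")
  }
  sub <- counts[allPos, , drop = FALSE]
  ref <- exp(rowMeans(log(sub)))
  sf <- apply(sub, 2L, function(col) stats::median(col / ref))
  names(sf) <- colnames(counts)
  sf
}

#' Normalize counts by size factors
#'
#' @param counts Count matrix (genes x samples).
#' @param sizeFactors Positive per-sample factors; estimated by
#'   [sizeFactorsMedianRatios()] when omitted.
#' @return Matrix of `counts[, j] / sizeFactors[j]`.
#' @export
normalizeCounts <- function(counts, sizeFactors = NULL) {
  if (is(counts, "TripletCountSet")) counts <- counts(counts)
  .assertCountMatrix(counts)
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatios(counts)
  if (length(sizeFactors) != ncol(counts) || any(sizeFactors <= 0)) {
    stop("'sizeFactors' must be positive, one per sample")
  }
  sweep(counts, 2L, sizeFactors, "/")
}

#' FPKM from counts, gene lengths and mapped totals
#'
#' `FPKM[g, j] = counts[g, j] * 1e9 / (length[g] * mappedTotal[j])`.
#'
#' @param counts Count matrix (genes x samples).
#' @param geneLengths Positive gene lengths in bp, one per gene.
#' @param mappedTotals Positive per-sample mapped fragment totals; column
#'   sums of `counts` when omitted.
#' @return Matrix of FPKM values.
#' @examples
#' computeFPKM(matrix(10), geneLengths = 1000, mappedTotals = 1e6)
#' @export
computeFPKM <- function(counts, geneLengths, mappedTotals = NULL) {
  if (is(counts, "TripletCountSet")) {
    if (missing(geneLengths)) geneLengths <- rowData(counts)$gene_length
    counts <- counts(counts)
  }
  .assertCountMatrix(counts)
  if (is.null(mappedTotals)) mappedTotals <- colSums(counts)
  if (length(geneLengths) != nrow(counts) || any(geneLengths <= 0) ||
      any(is.na(geneLengths))) {
    stop("'geneLengths' must be positive, one per gene")
  }
  if (length(mappedTotals) != ncol(counts) || any(mappedTotals <= 0)) {
    stop("'mappedTotals' must be positive, one per sample")
  }
  counts * 1e9 / outer(geneLengths, mappedTotals)
}

#' Correlation between two biological replicates
#'
#' Pearson correlation across genes of `log2(x + 1)` on normalized counts
#' of the two replicate columns.
#'
#' @param normCounts Matrix with exactly two normalized replicate columns,
#'   or a [TripletCountSet-class] (then `line` selects the replicate pair
#'   and counts are normalized by median-of-ratios factors over all
#'   samples).
#' @param line Line identifier, required for a `TripletCountSet`.
#' @return Pearson correlation coefficient in [-1, 1].
#' @export
replicateCorrelation <- function(normCounts, line = NULL) {
  if (is(normCounts, "TripletCountSet")) {
    if (is.null(line)) stop("'line' is required for a TripletCountSet")
    norm <- normalizeCounts(counts(normCounts))
    normCounts <- norm[, colData(normCounts)$line == line, drop = FALSE]
  }
  if (ncol(normCounts) != 2L) {
    stop("exactly two replicate columns are required")
  }
  x <- log2(normCounts[, 1L] + 1)
  y <- log2(normCounts[, 2L] + 1)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant replicate vector: correlation undefined")
  }
  stats::cor(x, y)
}

#' Average replicate columns into per-line expression
#'
#' Arithmetic mean per gene across each line's replicate columns (the
#' per-line expression level used downstream).
#'
#' @param values Expression matrix (genes x samples), e.g. normalized
#'   counts or FPKM.
#' @param lines Line identifier per column; taken from `colData` for a
#'   [TripletCountSet-class] (which is averaged on its raw counts).
#' @return Matrix with one column per line, in first-appearance order.
#' @export
averageReplicates <- function(values, lines = NULL) {
  if (is(values, "TripletCountSet")) {
    lines <- colData(values)$line
    values <- counts(values)
  }
  if (is.null(lines) || length(lines) != ncol(values)) {
    stop("'lines' must give one line per column")
  }
  uniq <- unique(lines)
  out <- vapply(uniq, function(l) {
    rowMeans(values[, lines == l, drop = FALSE])
  }, numeric(nrow(values)))
  if (is.vector(out)) out <- matrix(out, nrow = 1L)
  dimnames(out) <- list(rownames(values), uniq)
  out
}
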