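# Per-gene method-of-moments NB dispersion pooled across two groups, then
# smoothed by a parametric mean-dispersion trend alpha(mu) = a0 + a1 / mu.
# With two replicates per group the raw per-gene estimates carry ~1 df each
# and a Wald test built on them is badly anticalibrated; the trend borrows
# strength across genes, restoring near-nominal type I error while keeping
# the mean-variance relation Var = mu + alpha * mu^2.
.dispersionTrend <- function(m1, m2, v1, v2, n1, n2) {
  a1 <- ifelse(m1 > 0, (v1 - m1) / m1^2, NA_real_)
  a2 <- ifelse(m2 > 0, (v2 - m2) / m2^2, NA_real_)
  w1 <- n1 - 1L; w2 <- n2 - 1L
  amom <- ifelse(is.na(a1), a2,
          ifelse(is.na(a2), a1, (w1 * a1 + w2 * a2) / (w1 + w2)))
  mu <- (m1 + m2) / 2
  use <- !is.na(amom) & mu > 1
  if (sum(use) < 10L) {
    a0 <- stats::median(amom[!is.na(amom)], na.rm = TRUE)
    if (!is.finite(a0)) a0 <- 0.1
    coefs <- c(max(a0, 1e-8), 0)
  } else {
    a <- amom[use]
    qs <- stats::quantile(a, c(0.01, 0.99), na.rm = TRUE)
    a <- pmin(pmax(a, qs[1L]), qs[2L])   # winsorize MoM outliers
    x <- 1 / mu[use]
    fit <- stats::lm.fit(cbind(1, x), a)
    coefs <- fit$coefficients
    if (!all(is.finite(coefs))) coefs <- c(stats::median(a), 0)
  }
  pmax(coefs[1L] + coefs[2L] / pmax(mu, 1e-8), 1e-8)
}

#' Two-group negative-binomial differential expression test
#'
#' Per-gene Wald test of the log difference of normalized group means under
#' an NB model (variance `mu + alpha * mu^2`). Dispersion is estimated per
#' gene by method of moments pooled across the two groups and smoothed by a
#' parametric mean-dispersion trend fitted over all genes. The reported
#' fold change is `log2((m2 + 1) / (m1 + 1))` (pseudocount keeps it
#' finite), and a gene is flagged differential under the joint criteria
#' raw p < `pThreshold` and |log2 FC| > `lfcThreshold`. BH-adjusted
#' p-values are reported alongside but do not enter the call.
#'
#' @param counts1,counts2 Count (or already-normalized) matrices for the
#'   two groups, >= 2 columns each, same genes in the same order.
#' @param sizeFactors1,sizeFactors2 Per-sample size factors (default 1,
#'   i.e. inputs already normalized); see [sizeFactorsMedianRatios()].
#' @param pThreshold,lfcThreshold DEG criteria (defaults 0.05 and 1).
#' @return A [S4Vectors::DataFrame] with `gene_id`, `baseMean1`,
#'   `baseMean2`, `log2FoldChange`, `dispersion`, `stat`, `pvalue`, `padj`
#'   and `isDEG`. All-zero genes get `pvalue = 1`, `log2FoldChange = 0`.
#' @examples
#' set.seed(1)
#' y1 <- matrix(rnbinom(200, mu = 50, size = 10), 100)
#' y2 <- matrix(rnbinom(200, mu = 50, size = 10), 100)
#' res <- testDifferential(y1, y2)
#' sum(res$isDEG)
#' @export
testDifferential <- function(counts1, counts2,
                             sizeFactors1 = NULL, sizeFactors2 = NULL,
                             pThreshold = 0.05, lfcThreshold = 1) {
  .assertCountMatrix(counts1)
  .assertCountMatrix(counts2)
  if (nrow(counts1) != nrow(counts2)) {
    stop("the two groups must share the same gene universe")
  }
  n1 <- ncol(counts1); n2 <- ncol(counts2)
  if (n1 < 2L || n2 < 2L) {
    stop("each group needs >= 2 samples to estimate dispersion")
  }
  if (!is.null(sizeFactors1)) {
    counts1 <- normalizeCounts(counts1, sizeFactors1)
  }
  if (!is.null(sizeFactors2)) {
    counts2 <- normalizeCounts(counts2, sizeFactors2)
  }
  m1 <- unname(rowMeans(counts1)); m2 <- unname(rowMeans(counts2))
  v1 <- unname(apply(counts1, 1L, stats::var))
  v2 <- unname(apply(counts2, 1L, stats::var))
  alpha <- .dispersionTrend(m1, m2, v1, v2, n1, n2)

  log2fc <- log2((m2 + 1) / (m1 + 1))
  # delta method on log means; the +1 pseudocount also guards the Poisson
  # term for all-zero groups
  se <- sqrt(1 / (n1 * (m1 + 1)) + alpha / n1 +
             1 / (n2 * (m2 + 1)) + alpha / n2)
  stat <- (log(m2 + 1) - log(m1 + 1)) / se
  pvalue <- 2 * stats::pnorm(-abs(stat))
  zero <- m1 == 0 & m2 == 0
  pvalue[zero] <- 1
  stat[zero] <- 0
  log2fc[zero] <- 0
  geneIds <- rownames(counts1)
  if (is.null(geneIds)) geneIds <- sprintf("gene%05d", seq_along(m1))
  res <- DataFrame(gene_id = geneIds, baseMean1 = m1, baseMean2 = m2,
                   log2FoldChange = log2fc, dispersion = alpha,
                   stat = stat, pvalue = pvalue,
                   padj = stats::p.adjust(pvalue, method = "BH"),
                   row.names = geneIds)
  res$isDEG <- res$pvalue < pThreshold & abs(res$log2FoldChange) > lfcThreshold
  res
}

#' Differential genes between two lines of a TripletCountSet
#'
#' Convenience wrapper: extracts the two lines' replicate columns,
#' estimates median-of-ratios size factors over all samples of the object,
#' and runs [testDifferential()] (line1 as group 1).
#'
#' @param object A [TripletCountSet-class].
#' @param line1,line2 Line identifiers.
#' @param ... Passed to [testDifferential()].
#' @return See [testDifferential()].
#' @export
testLinePair <- function(object, line1, line2, ...) {
  stopifnot(is(object, "TripletCountSet"))
  sf <- sizeFactorsMedianRatios(counts(object))
  norm <- normalizeCounts(counts(object), sf)
  ln <- colData(object)$line
  testDifferential(norm[, ln == line1, drop = FALSE],
                   norm[, ln == line2, drop = FALSE], ...)
}
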