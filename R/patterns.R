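.PATTERN_LEVELS <- c("additive", "high_parent_dominance",
                     "low_parent_dominance", "over_dominance",
                     "under_dominance", "ambiguous")

#' Mid-parent pseudo-replicates
#'
#' Pairs replicate i of each parent and takes the rounded mean of their
#' normalized counts, yielding mid-parent (MP) pseudo-samples on which the
#' same NB test as for real samples can run (their size factors are 1 by
#' construction).
#'
#' @param parent1,parent2 Normalized count matrices with equal, matching
#'   replicate columns.
#' @return Matrix of MP pseudo-replicates.
#' @examples
#' buildMidparentPseudosamples(matrix(10, 2, 2), matrix(30, 2, 2))
#' @export
buildMidparentPseudosamples <- function(parent1, parent2) {
  if (!is.matrix(parent1)) parent1 <- as.matrix(parent1)
  if (!is.matrix(parent2)) parent2 <- as.matrix(parent2)
  if (ncol(parent1) != ncol(parent2)) {
    stop("unequal replicate numbers between parents; replicates are paired, ",
         "not recycled")
  }
  if (nrow(parent1) != nrow(parent2)) stop("gene universes differ")
  mp <- round((parent1 + parent2) / 2)
  colnames(mp) <- paste0("MP-", seq_len(ncol(mp)))
  mp
}

.normalizeTriplet <- function(hybrid, parent1, parent2, sizeFactors = NULL) {
  all <- cbind(parent1, parent2, hybrid)
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatios(all)
  norm <- normalizeCounts(all, sizeFactors)
  i1 <- seq_len(ncol(parent1))
  i2 <- ncol(parent1) + seq_len(ncol(parent2))
  ih <- ncol(parent1) + ncol(parent2) + seq_len(ncol(hybrid))
  list(parent1 = norm[, i1, drop = FALSE], parent2 = norm[, i2, drop = FALSE],
       hybrid = norm[, ih, drop = FALSE])
}

#' Call non-additively expressed genes in a triplet
#'
#' Builds MP pseudo-replicates from the two parents' normalized counts and
#' tests the hybrid against them with [testDifferential()]; a gene is
#' non-additive when it meets the joint criteria (raw p < `pThreshold`,
#' |log2 FC| > `lfcThreshold`) in the hybrid-vs-MP comparison.
#'
#' @param hybrid,parent1,parent2 Count matrices (>= 2 replicate columns
#'   each, shared gene universe).
#' @param sizeFactors Optional per-sample factors for
#'   `cbind(parent1, parent2, hybrid)`; estimated by median-of-ratios when
#'   omitted.
#' @param pThreshold,lfcThreshold Joint criteria (defaults 0.05, 1).
#' @return The [testDifferential()] result (MP as group 1, hybrid as group
#'   2) with an extra logical column `nonadditive` (`== isDEG`).
#' @export
callNonadditive <- function(hybrid, parent1, parent2, sizeFactors = NULL,
                            pThreshold = 0.05, lfcThreshold = 1) {
  nt <- .normalizeTriplet(hybrid, parent1, parent2, sizeFactors)
  mp <- buildMidparentPseudosamples(nt$parent1, nt$parent2)
  res <- testDifferential(mp, nt$hybrid, pThreshold = pThreshold,
                          lfcThreshold = lfcThreshold)
  res$nonadditive <- res$isDEG
  res
}

#' Classify hybrid expression patterns in a triplet
#'
#' Runs the hybrid-vs-MP, hybrid-vs-parent1 and hybrid-vs-parent2 NB tests
#' and assigns each gene one of the five expression modes (plus a total
#' `ambiguous` class):
#' \itemize{
#'   \item `additive` - hybrid not differential from MP;
#'   \item `over_dominance` - differential from MP and significantly above
#'     the (per-gene) high parent;
#'   \item `under_dominance` - significantly below the low parent;
#'   \item `high_parent_dominance` / `low_parent_dominance` - differential
#'     from MP, indistinguishable from one parent while differential from
#'     the other;
#'   \item `ambiguous` - differential from MP but matching none of the
#'     named modes.
#' }
#' "Significant" throughout means the joint criteria raw p < `pThreshold`
#' and |log2 FC| > `lfcThreshold`. High and low parent are decided per
#' gene by normalized line means, so labels are invariant to the order the
#' parents are given in.
#'
#' @inheritParams callNonadditive
#' @return A [S4Vectors::DataFrame] with per-gene line means
#'   (`parent1Mean`, `parent2Mean`, `mpValue`, `hybridMean`), the
#'   hybrid-vs-MP test columns (`log2FoldChangeMP`, `pvalueMP`,
#'   `nonadditive`), `withinParentalRange`, and `pattern`.
#' @export
classifyPatterns <- function(hybrid, parent1, parent2, sizeFactors = NULL,
                             pThreshold = 0.05, lfcThreshold = 1) {
  nt <- .normalizeTriplet(hybrid, parent1, parent2, sizeFactors)
  vsMP <- callNonadditive(hybrid, parent1, parent2, sizeFactors,
                          pThreshold, lfcThreshold)
  vsP1 <- testDifferential(nt$parent1, nt$hybrid, pThreshold = pThreshold,
                           lfcThreshold = lfcThreshold)
  vsP2 <- testDifferential(nt$parent2, nt$hybrid, pThreshold = pThreshold,
                           lfcThreshold = lfcThreshold)
  m1 <- rowMeans(nt$parent1)
  m2 <- rowMeans(nt$parent2)
  mh <- rowMeans(nt$hybrid)
  p1High <- m1 >= m2
  hiMean <- ifelse(p1High, m1, m2)
  loMean <- ifelse(p1High, m2, m1)
  sigHi <- ifelse(p1High, vsP1$isDEG, vsP2$isDEG)
  lfcHi <- ifelse(p1High, vsP1$log2FoldChange, vsP2$log2FoldChange)
  sigLo <- ifelse(p1High, vsP2$isDEG, vsP1$isDEG)
  lfcLo <- ifelse(p1High, vsP2$log2FoldChange, vsP1$log2FoldChange)

  pattern <- rep("ambiguous", length(mh))
  pattern[!vsMP$nonadditive] <- "additive"
  na <- vsMP$nonadditive
  over <- na & mh > hiMean & sigHi & lfcHi > 0
  under <- na & mh < loMean & sigLo & lfcLo < 0
  hidom <- na & !over & !under & !sigHi & sigLo
  lodom <- na & !over & !under & !sigLo & sigHi
  pattern[over] <- "over_dominance"
  pattern[under] <- "under_dominance"
  pattern[hidom] <- "high_parent_dominance"
  pattern[lodom] <- "low_parent_dominance"

  DataFrame(gene_id = vsMP$gene_id,
            parent1Mean = m1, parent2Mean = m2,
            mpValue = (m1 + m2) / 2, hybridMean = mh,
            log2FoldChangeMP = vsMP$log2FoldChange,
            pvalueMP = vsMP$pvalue,
            nonadditive = vsMP$nonadditive,
            withinParentalRange = mh >= loMean & mh <= hiMean,
            pattern = factor(pattern, levels = .PATTERN_LEVELS),
            row.names = vsMP$gene_id)
}

#' Parental-range classification of hybrid line means
#'
#' A gene is within the parental range when its replicate-averaged hybrid
#' mean lies in the closed interval between the two parents' line means
#' (inclusive bounds, no significance filter).
#'
#' @param parent1Mean,parent2Mean,hybridMean Numeric vectors of
#'   replicate-averaged per-line expression, one entry per gene.
#' @return A list with `within` (logical per gene) and `summary` (see
#'   [rangeSummary()]).
#' @export
classifyParentalRange <- function(parent1Mean, parent2Mean, hybridMean) {
  if (length(parent1Mean) != length(hybridMean) ||
      length(parent2Mean) != length(hybridMean)) {
    stop("line-mean vectors must have equal length")
  }
  within <- hybridMean >= pmin(parent1Mean, parent2Mean) &
            hybridMean <= pmax(parent1Mean, parent2Mean)
  list(within = within, summary = rangeSummary(sum(within), sum(!within)))
}

#' Within/out-of-parental-range summary arithmetic
#'
#' @param nWithin,nOut Gene counts inside and outside the parental range.
#' @return One-row data.frame with the counts, the total, and the two
#'   percentages (half-up, 2 decimals), which partition 100 up to
#'   rounding.
#' @examples
#' rangeSummary(16371, 8828)
#' @export
rangeSummary <- function(nWithin, nOut) {
  total <- nWithin + nOut
  if (total <= 0) stop("empty gene universe")
  data.frame(within = nWithin, out = nOut, total = total,
             within_pct = roundHalfUp(100 * nWithin / total, 2),
             out_pct = roundHalfUp(100 * nOut / total, 2))
}
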