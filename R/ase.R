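#' Assign reads to parental alleles from SNP match profiles
#'
#' A read is assigned to a parent when every informative SNP it covers
#' (positions where the two parental alleles differ) matches that parent's
#' allele and at least one informative SNP is covered; reads covering no
#' informative SNP are `ambiguous`; reads whose covered SNPs support
#' different parents (or match neither allele at some position) are
#' `conflicting`. Non-informative SNPs (equal parental alleles) are
#' excluded, not an error.
#'
#' @param profiles data.frame with one row per (read, covered SNP):
#'   columns `read_id`, `gene_id`, `observed`, `allele1`, `allele2`.
#' @return data.frame with one row per read: `read_id`, `gene_id`,
#'   `assignment` in `parent1`, `parent2`, `ambiguous`, `conflicting`.
#' @examples
#' pr <- data.frame(read_id = "r1", gene_id = "g1",
#'                  observed = c("A", "C"), allele1 = c("A", "C"),
#'                  allele2 = c("G", "T"))
#' assignReads(pr)
#' @export
assignReads <- function(profiles) {
  need <- c("read_id", "gene_id", "observed", "allele1", "allele2")
  if (!all(need %in% colnames(profiles))) {
    stop("'profiles' must have columns ", paste(need, collapse = ", "))
  }
  reads <- unique(profiles[, c("read_id", "gene_id")])
  if (anyDuplicated(reads$read_id)) {
    stop("a read_id maps to more than one gene_id")
  }
  inf <- profiles$allele1 != profiles$allele2
  pi <- profiles[inf, , drop = FALSE]
  nInf <- rowsum(rep(1L, nrow(pi)), pi$read_id)
  n1 <- rowsum(as.integer(pi$observed == pi$allele1), pi$read_id)
  n2 <- rowsum(as.integer(pi$observed == pi$allele2), pi$read_id)
  idx <- match(reads$read_id, rownames(nInf))
  covered <- ifelse(is.na(idx), 0L, nInf[idx])
  match1 <- ifelse(is.na(idx), 0L, n1[idx])
  match2 <- ifelse(is.na(idx), 0L, n2[idx])
  assignment <- rep("conflicting", nrow(reads))
  assignment[covered == 0L] <- "ambiguous"
  assignment[covered > 0L & match1 == covered] <- "parent1"
  assignment[covered > 0L & match2 == covered] <- "parent2"
  data.frame(read_id = reads$read_id, gene_id = reads$gene_id,
             assignment = assignment, stringsAsFactors = FALSE)
}

#' Aggregate read assignments into per-gene allelic counts
#'
#' Tallies `parent1` and `parent2` assignments per gene; `ambiguous` and
#' `conflicting` reads are excluded from the counts.
#'
#' @param assignments Output of [assignReads()] (columns `gene_id`,
#'   `assignment`).
#' @param genes Optional gene universe; genes without informative reads
#'   get (0, 0).
#' @return data.frame with `gene_id`, `n1`, `n2`.
#' @export
aggregateAllelicCounts <- function(assignments, genes = NULL) {
  if (!all(c("gene_id", "assignment") %in% colnames(assignments))) {
    stop("'assignments' must have gene_id and assignment columns")
  }
  if (is.null(genes)) genes <- unique(assignments$gene_id)
  n1 <- table(factor(assignments$gene_id[assignments$assignment == "parent1"],
                     levels = genes))
  n2 <- table(factor(assignments$gene_id[assignments$assignment == "parent2"],
                     levels = genes))
  data.frame(gene_id = genes, n1 = as.integer(n1), n2 = as.integer(n2),
             stringsAsFactors = FALSE)
}

#' Permutation-based allele-specific expression caller
#'
#' Tests each gene's allelic counts for deviation from a 1:1 ratio. The
#' two allele-count columns are first normalized with median-of-ratios
#' size factors computed on the two-column matrix over genes meeting the
#' depth filter. For each tested gene (normalized depth >= `minDepth`),
#' with `n = round(n1_norm + n2_norm)` and observed deviation
#' `d = |n1_norm - n/2|`, `B` Monte-Carlo draws `X_b ~ Binomial(n, 1/2)`
#' estimate the permutation p-value `(1 + #{|X_b - n/2| >= d}) / (B + 1)`.
#' Benjamini-Hochberg adjustment across tested genes yields `fdr_q`; a
#' gene has ASE when `fdr_q < fdrThreshold`.
#'
#' @param allelic data.frame with `gene_id`, `n1`, `n2` (see
#'   [aggregateAllelicCounts()]).
#' @param B Number of Monte-Carlo permutations (default 1000).
#' @param minDepth Minimum normalized informative depth to test a gene
#'   (default 10); genes below it are returned untested (`NA` p), never
#'   silently p = 1.
#' @param seed Optional integer seed for the permutation draws.
#' @param fdrThreshold FDR threshold for the ASE call (default 0.05).
#' @return The input with added columns `n1_norm`, `n2_norm`, `tested`,
#'   `perm_p`, `fdr_q`, `is_ase`, `biased_parent`.
#' @examples
#' tab <- data.frame(gene_id = c("g1", "g2"), n1 = c(50, 95), n2 = c(50, 5))
#' callASE(tab, B = 200, seed = 1)
#' @export
callASE <- function(allelic, B = 1000, minDepth = 10, seed = NULL,
                    fdrThreshold = 0.05) {
  if (!all(c("gene_id", "n1", "n2") %in% colnames(allelic))) {
    stop("'allelic' must have gene_id, n1, n2 columns")
  }
  if (B < 1) stop("'B' must be >= 1")
  if (minDepth < 1) stop("'minDepth' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(allelic)
  depthRaw <- out$n1 + out$n2
  deep <- depthRaw >= minDepth & out$n1 > 0 & out$n2 > 0
  if (sum(deep) >= 2L) {
    sf <- sizeFactorsMedianRatios(
      cbind(n1 = out$n1[deep], n2 = out$n2[deep]))
  } else {
    sf <- c(n1 = 1, n2 = 1)   # too few balanced genes to normalize
  }
  out$n1_norm <- out$n1 / sf[["n1"]]
  out$n2_norm <- out$n2 / sf[["n2"]]
  out$tested <- out$n1_norm + out$n2_norm >= minDepth
  out$perm_p <- NA_real_
  tested <- which(out$tested)
  if (length(tested)) {
    n <- round(out$n1_norm[tested] + out$n2_norm[tested])
    dObs <- abs(out$n1_norm[tested] - n / 2)
    exceed <- vapply(seq_along(tested), function(i) {
      draws <- stats::rbinom(B, n[i], 0.5)
      sum(abs(draws - n[i] / 2) >= dObs[i] - 1e-9)
    }, numeric(1L))
    out$perm_p[tested] <- (1 + exceed) / (B + 1)
  }
  out$fdr_q <- NA_real_
  out$fdr_q[tested] <- stats::p.adjust(out$perm_p[tested], method = "BH")
  out$is_ase <- !is.na(out$fdr_q) & out$fdr_q < fdrThreshold
  out$biased_parent <- ifelse(out$n1_norm >= out$n2_norm, "parent1",
                              "parent2")
  out$biased_parent[!out$is_ase] <- NA_character_
  out
}

#' Read a parental SNP table
#'
#' Five-column TSV (`chrom`, `pos`, `parent1_allele`, `parent2_allele`,
#' `gene_id`), coordinates 0-based half-open; only rows where the two
#' parental alleles differ are informative (kept with a flag).
#'
#' @param path Path to the TSV.
#' @return data.frame with the five columns and `informative`.
#' @export
readSnpTable <- function(path) {
  snp <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "parent1_allele", "parent2_allele", "gene_id")
  if (!all(need %in% colnames(snp))) {
    stop("SNP table must have columns ", paste(need, collapse = ", "))
  }
  snp$informative <- snp$parent1_allele != snp$parent2_allele
  snp
}

#' Read biallelic SNPs from a VCF and assign them to genes
#'
#' Keeps biallelic single-nucleotide records (REF as the parent-1 allele,
#' ALT as the parent-2 allele), converts the 1-based VCF positions to the
#' package's 0-based half-open convention, and assigns each SNP to the
#' gene whose range overlaps it.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @param genes A [GenomicRanges::GRanges] of gene ranges with a `gene_id`
#'   metadata column, or a data.frame with `chrom`, `start`, `end`,
#'   `gene_id` (1-based closed coordinates).
#' @return A SNP table as from [readSnpTable()]; SNPs outside any gene are
#'   dropped.
#' @export
readSnpVcf <- function(path, genes) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("package 'vcfR' is required to read VCF input")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE)
  fix <- fix[keep, , drop = FALSE]
  if (is.data.frame(genes)) {
    genes <- GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = genes$start, end = genes$end),
      gene_id = genes$gene_id)
  }
  snpGr <- GenomicRanges::GRanges(
    seqnames = fix$CHROM,
    ranges = IRanges::IRanges(start = as.integer(fix$POS), width = 1L))
  hit <- GenomicRanges::findOverlaps(snpGr, genes, select = "first")
  keep <- !is.na(hit)
  data.frame(chrom = fix$CHROM[keep],
             pos = as.integer(fix$POS[keep]) - 1L,   # to 0-based
             parent1_allele = fix$REF[keep],
             parent2_allele = fix$ALT[keep],
             gene_id = S4Vectors::mcols(genes)$gene_id[hit[keep]],
             informative = fix$REF[keep] != fix$ALT[keep],
             stringsAsFactors = FALSE)
}
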