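.NA_MODES <- c("high_parent_dominance", "low_parent_dominance",
               "over_dominance", "under_dominance")

#' Configure the triplet count simulator
#'
#' Builds a [SimulationConfig-class] with defaults emulating a four-parent
#' half-diallel RNA-seq study: 2 replicates per line, log-normal baseline
#' expression, NB counts (variance `mu + dispersion * mu^2`), library sizes
#' drawn on the 13-22 million read scale, and planted effect structure.
#'
#' @param nGenes,nReplicates Design size (defaults 10000 genes, 2
#'   replicates).
#' @param lines Parent line identifiers; the hybrids are the half-diallel
#'   without reciprocals.
#' @param baselineLogMean,baselineLogSd Log-normal (natural-log) parameters
#'   of per-gene relative expression means.
#' @param dispersion NB dispersion, scalar or per gene.
#' @param librarySizes Per-sample expected totals; `NULL` draws each
#'   uniformly in [13e6, 22e6].
#' @param fracDEG Fraction of genes planted as differential in one randomly
#'   chosen parent; `degLog2FC` the planted |log2 fold change| (random
#'   sign).
#' @param fracNonadditive Fraction of genes whose hybrid means are moved
#'   off the mid-parent value; `nonadditiveModeMix` the mode proportions;
#'   `nonadditiveLog2Deviation` the log2 deviation from mid-parent planted
#'   for over/under-dominance; `overdominanceMargin` the minimum log2
#'   margin beyond the extreme parent.
#' @param fracCisASE Fraction of genes with allelic bias in hybrids;
#'   `cisBias` the parent-1 allele probability for those genes.
#' @param informativeFracMean,informativeFracConc Beta(mean, concentration)
#'   model for the per-gene fraction of reads covering an informative SNP.
#' @param geneLengthRange Log-uniform gene-length range in bp.
#' @param seed Integer RNG seed.
#' @return A validated [SimulationConfig-class].
#' @examples
#' simulationConfig(nGenes = 100, librarySizes = 1e5, seed = 7)
#' @export
simulationConfig <- function(nGenes = 10000, nReplicates = 2,
                             lines = c("T121", "T126", "PH4CV", "PH6WC"),
                             baselineLogMean = 4, baselineLogSd = 1.5,
                             dispersion = 0.05, librarySizes = NULL,
                             fracDEG = 0.1, degLog2FC = 2,
                             fracNonadditive = 0.05,
                             nonadditiveModeMix = c(
                               high_parent_dominance = 0.25,
                               low_parent_dominance = 0.25,
                               over_dominance = 0.25,
                               under_dominance = 0.25),
                             nonadditiveLog2Deviation = 2,
                             overdominanceMargin = 0.5,
                             fracCisASE = 0.1, cisBias = 0.8,
                             informativeFracMean = 0.3,
                             informativeFracConc = 10,
                             geneLengthRange = c(500, 5000), seed = 1) {
  cfg <- new("SimulationConfig",
    nGenes = .assertScalarCount(nGenes, "nGenes"),
    nReplicates = .assertScalarCount(nReplicates, "nReplicates"),
    lines = as.character(lines),
    baselineLogMean = as.numeric(baselineLogMean),
    baselineLogSd = as.numeric(baselineLogSd),
    dispersion = as.numeric(dispersion),
    librarySizes = if (is.null(librarySizes)) NA_real_
                   else as.numeric(librarySizes),
    fracDEG = .assertFraction(fracDEG, "fracDEG"),
    degLog2FC = as.numeric(degLog2FC),
    fracNonadditive = .assertFraction(fracNonadditive, "fracNonadditive"),
    nonadditiveModeMix = nonadditiveModeMix,
    nonadditiveLog2Deviation = as.numeric(nonadditiveLog2Deviation),
    overdominanceMargin = as.numeric(overdominanceMargin),
    fracCisASE = .assertFraction(fracCisASE, "fracCisASE"),
    cisBias = .assertFraction(cisBias, "cisBias"),
    informativeFracMean = informativeFracMean,
    informativeFracConc = as.numeric(informativeFracConc),
    geneLengthRange = as.numeric(geneLengthRange),
    seed = as.integer(seed))
  validObject(cfg)
  cfg
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes x",
      length(object@lines), "parents x", object@nReplicates,
      "replicates (seed ", object@seed, ")\n", sep = " ")
  cat("  planted: fracDEG =", object@fracDEG,
      "| fracNonadditive =", object@fracNonadditive,
      "| fracCisASE =", object@fracCisASE, "\n")
})

#' Simulate an allele-resolved parent-hybrid triplet dataset
#'
#' Draws NB counts for every parent and half-diallel hybrid under the
#' configured design. Parent means are log-normal; planted differential
#' genes shift one parent by `2^(+/- degLog2FC)`. Hybrid means equal the
#' mid-parent of the two parental means except planted non-additive genes:
#' dominance modes move the hybrid to the extreme parent (realized only in
#' hybrids whose parents differ for that gene), over/under-dominance place
#' it `nonadditiveLog2Deviation` log2 units beyond mid-parent and at least
#' `overdominanceMargin` beyond the extreme parent. Hybrid informative
#' reads (a Beta-distributed fraction of each gene's total) split
#' binomially between parental alleles with probability 0.5, or `cisBias`
#' for planted cis genes. A fixed seed reproduces the dataset exactly.
#'
#' @param config A [SimulationConfig-class].
#' @return A [SyntheticTriplets-class] with counts, allelic counts, gene
#'   lengths (in `rowData`), expected means and a per-gene truth table
#'   (`is_deg`, `deg_parent`, `true_log2fc`, `nonadditive_mode`,
#'   `is_cis_ase`, `allele1_prob`, and one realized pattern column per
#'   hybrid).
#' @examples
#' sim <- simulateTriplets(simulationConfig(nGenes = 50, librarySizes = 5e4))
#' sim
#' @export
simulateTriplets <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  nG <- config@nGenes
  parents <- config@lines
  design <- tripletDesign(parents)
  tr <- triplets(design)
  hybrids <- tr$hybrid
  geneIds <- sprintf("gene%05d", seq_len(nG))

  baseMu <- stats::rlnorm(nG, config@baselineLogMean, config@baselineLogSd)
  lambda <- matrix(baseMu, nG, length(parents),
                   dimnames = list(geneIds, parents))

  ## planted parental differential expression
  nDEG <- round(config@fracDEG * nG)
  degGenes <- if (nDEG > 0) sample.int(nG, nDEG) else integer(0)
  degParent <- rep(NA_character_, nG)
  trueLog2fc <- rep(0, nG)
  if (nDEG > 0) {
    degParent[degGenes] <- sample(parents, nDEG, replace = TRUE)
    sgn <- sample(c(-1, 1), nDEG, replace = TRUE)
    trueLog2fc[degGenes] <- sgn * config@degLog2FC
    idx <- cbind(degGenes, match(degParent[degGenes], parents))
    lambda[idx] <- lambda[idx] * 2^trueLog2fc[degGenes]
  }

  ## planted non-additive genes (disjoint from DEG genes so each truth label
  ## isolates one effect)
  nNA <- round(config@fracNonadditive * nG)
  pool <- setdiff(seq_len(nG), degGenes)
  naGenes <- if (nNA > 0) sample(pool, min(nNA, length(pool))) else integer(0)
  naMode <- rep("none", nG)
  if (length(naGenes)) {
    naMode[naGenes] <- sample(.NA_MODES, length(naGenes), replace = TRUE,
                              prob = config@nonadditiveModeMix)
  }

  ## hybrid expected means and realized per-hybrid pattern labels
  dev <- 2^config@nonadditiveLog2Deviation
  marg <- 2^config@overdominanceMargin
  lambdaH <- matrix(0, nG, length(hybrids),
                    dimnames = list(geneIds, hybrids))
  patterns <- matrix("additive", nG, length(hybrids),
                     dimnames = list(geneIds, hybrids))
  for (j in seq_along(hybrids)) {
    l1 <- lambda[, tr$parent1[j]]
    l2 <- lambda[, tr$parent2[j]]
    hi <- pmax(l1, l2); lo <- pmin(l1, l2); mp <- (l1 + l2) / 2
    lh <- mp
    over <- naMode == "over_dominance"
    under <- naMode == "under_dominance"
    hidom <- naMode == "high_parent_dominance" & hi > lo
    lodom <- naMode == "low_parent_dominance" & hi > lo
    lh[over] <- pmax(hi[over] * marg, mp[over] * dev)
    lh[under] <- pmin(lo[under] / marg, mp[under] / dev)
    lh[hidom] <- hi[hidom]
    lh[lodom] <- lo[lodom]
    patterns[over, j] <- "over_dominance"
    patterns[under, j] <- "under_dominance"
    patterns[hidom, j] <- "high_parent_dominance"
    patterns[lodom, j] <- "low_parent_dominance"
    lambdaH[, j] <- lh
  }
  lambdaAll <- cbind(lambda, lambdaH)

  ## sample sheet and library sizes
  allLines <- colnames(lambdaAll)
  nRep <- config@nReplicates
  sampleLine <- rep(allLines, each = nRep)
  sampleRep <- rep(seq_len(nRep), times = length(allLines))
  nSamples <- length(sampleLine)
  libSizes <- config@librarySizes
  if (all(is.na(libSizes))) {
    libSizes <- stats::runif(nSamples, 13e6, 22e6)
  } else {
    libSizes <- rep_len(libSizes, nSamples)
  }

  size <- 1 / rep_len(config@dispersion, nG)
  cts <- matrix(0L, nG, nSamples)
  for (s in seq_len(nSamples)) {
    lam <- lambdaAll[, sampleLine[s]]
    mu <- lam / sum(lam) * libSizes[s]
    cts[, s] <- stats::rnbinom(nG, mu = mu, size = size)
  }
  dimnames(cts) <- list(geneIds, paste(sampleLine, sampleRep, sep = "-"))

  geneLengths <- round(exp(stats::runif(nG,
                                        log(config@geneLengthRange[1L]),
                                        log(config@geneLengthRange[2L]))))

  ## allelic split of hybrid informative reads
  nCis <- round(config@fracCisASE * nG)
  cisGenes <- if (nCis > 0) sample.int(nG, nCis) else integer(0)
  allele1Prob <- rep(0.5, nG)
  allele1Prob[cisGenes] <- config@cisBias
  m <- config@informativeFracMean
  conc <- config@informativeFracConc
  infFrac <- if (m <= 0 || m >= 1) rep(m, nG) else
    stats::rbeta(nG, m * conc, (1 - m) * conc)
  allelic <- SimpleList(lapply(hybrids, function(h) {
    tot <- rowSums(cts[, sampleLine == h, drop = FALSE])
    nInfo <- stats::rbinom(nG, tot, infFrac)
    n1 <- stats::rbinom(nG, nInfo, allele1Prob)
    DataFrame(gene_id = geneIds, n1 = n1, n2 = nInfo - n1)
  }))
  names(allelic) <- hybrids

  truth <- DataFrame(
    gene_id = geneIds,
    is_deg = seq_len(nG) %in% degGenes,
    deg_parent = degParent,
    true_log2fc = trueLog2fc,
    nonadditive_mode = naMode,
    is_cis_ase = seq_len(nG) %in% cisGenes,
    allele1_prob = allele1Prob,
    row.names = geneIds)
  for (h in hybrids) truth[[paste0("pattern_", h)]] <- patterns[, h]

  tcs <- TripletCountSet(cts, line = sampleLine, replicate = sampleRep,
                         design = design, geneLengths = geneLengths)
  metadata(tcs)$library_sizes <- libSizes
  obj <- new("SyntheticTriplets", counts = tcs, allelic = allelic,
             truth = truth, expectedMeans = lambdaAll, config = config)
  validObject(obj)
  obj
}

#' Write a simulated dataset as TSV files
#'
#' Writes `counts.tsv`, `sample_sheet.tsv`, `gene_lengths.tsv`,
#' `truth.tsv` and one `allelic_<hybrid>.tsv` per hybrid under `dir`.
#'
#' @param x A [SyntheticTriplets-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeTriplets <- function(x, dir) {
  stopifnot(is(x, "SyntheticTriplets"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tcs <- tripletCounts(x)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "sample_sheet.tsv"),
    lengths = file.path(dir, "gene_lengths.tsv"),
    truth = file.path(dir, "truth.tsv"))
  writeCountMatrix(counts(tcs), paths["counts"])
  cd <- colData(tcs)
  utils::write.table(
    data.frame(sample_id = rownames(cd), line = cd$line,
               replicate = cd$replicate, role = cd$role),
    paths["samples"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = rownames(tcs),
               length = rowData(tcs)$gene_length),
    paths["lengths"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(truthLabels(x)), paths["truth"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (h in names(allelicCounts(x))) {
    p <- file.path(dir, paste0("allelic_", h, ".tsv"))
    utils::write.table(as.data.frame(allelicCounts(x)[[h]]), p,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths[paste0("allelic_", h)] <- p
  }
  invisible(paths)
}
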