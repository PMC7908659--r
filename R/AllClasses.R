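#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<- rowData<-
NULL

#' TripletDesign: a half-diallel registry of parent-hybrid triplets
#'
#' Registry of the crossing design: a set of inbred parent lines and the
#' triplets (parent1, parent2, hybrid) formed by crossing them without
#' reciprocals or self-crosses.  The default design of four parents yields
#' six hybrids, each parent participating in three triplets (a "joint
#' netted" pattern).
#'
#' @slot parents Character vector of parent line identifiers.
#' @slot triplets A `data.frame` with columns `parent1`, `parent2`,
#'   `hybrid`, one row per cross.
#' @seealso [tripletDesign()]
#' @export
setClass("TripletDesign",
  representation(parents = "character", triplets = "data.frame"))

setValidity("TripletDesign", function(object) {
  p <- object@parents
  tr <- object@triplets
  msgs <- character()
  if (anyDuplicated(p)) msgs <- c(msgs, "duplicated parent identifiers")
  if (!all(c("parent1", "parent2", "hybrid") %in% colnames(tr))) {
    msgs <- c(msgs, "'triplets' must have columns parent1, parent2, hybrid")
  } else {
    if (!all(c(tr$parent1, tr$parent2) %in% p)) {
      msgs <- c(msgs, "triplet parents must be registered parent lines")
    }
    if (any(tr$parent1 == tr$parent2)) {
      msgs <- c(msgs, "self-crosses are not allowed")
    }
    key <- apply(cbind(tr$parent1, tr$parent2), 1L,
                 function(x) paste(sort(x), collapse = "\r"))
    if (anyDuplicated(key)) {
      msgs <- c(msgs, "reciprocal or duplicated crosses are not allowed")
    }
    if (anyDuplicated(tr$hybrid)) {
      msgs <- c(msgs, "duplicated hybrid identifiers")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' TripletCountSet: gene-level counts for a triplet experiment
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying a `counts` assay
#' (genes x samples, non-negative) whose `colData` records each sample's
#' `line`, `replicate` and `role` (`"parent"` or `"hybrid"`), with the
#' [TripletDesign-class] stored in the object metadata and optional gene
#' lengths in `rowData`.
#'
#' @seealso [TripletCountSet()], [tripletCounts()]
#' @export
setClass("TripletCountSet", contains = "SummarizedExperiment")

setValidity("TripletCountSet", function(object) {
  msgs <- character()
  if (!"counts" %in% names(assays(object))) {
    return("assay 'counts' is required")
  }
  cts <- assay(object, "counts")
  if (any(is.na(cts)) || any(cts < 0)) {
    msgs <- c(msgs, "counts must be non-negative with no missing values")
  }
  cd <- colData(object)
  need <- c("line", "replicate", "role")
  if (!all(need %in% colnames(cd))) {
    msgs <- c(msgs, paste("colData must contain", paste(need, collapse = ", ")))
  } else if (!all(cd$role %in% c("parent", "hybrid"))) {
    msgs <- c(msgs, "role must be 'parent' or 'hybrid'")
  }
  if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: parameters of the triplet count simulator
#'
#' Holds every tunable of [simulateTriplets()]: design size, negative
#' binomial expression model, library sizes, and the fractions/effect sizes
#' of planted differentially expressed, non-additive and cis-biased genes.
#' Construct with [simulationConfig()], which supplies study-scale defaults.
#'
#' @slot nGenes,nReplicates Integer design size.
#' @slot lines Parent line identifiers (hybrids are derived as the
#'   half-diallel without reciprocals).
#' @slot baselineLogMean,baselineLogSd Log-normal parameters of per-gene
#'   relative expression means.
#' @slot dispersion NB dispersion (scalar or per gene); variance is
#'   `mu + dispersion * mu^2`.
#' @slot librarySizes Expected total counts per sample, or `NA` to draw
#'   uniformly on the 13-22 million read scale of a typical library.
#' @slot fracDEG,degLog2FC Fraction of genes planted as differentially
#'   expressed in one randomly chosen parent, and the planted |log2 FC|.
#' @slot fracNonadditive,nonadditiveModeMix,nonadditiveLog2Deviation,
#'   overdominanceMargin Non-additive planting: fraction, mix over the four
#'   modes, the log2 deviation from mid-parent used for over/under-dominance,
#'   and the minimum log2 margin beyond the extreme parent.
#' @slot fracCisASE,cisBias Fraction of genes with allelic bias in hybrids
#'   and the parent-1 allele probability for those genes.
#' @slot informativeFracMean,informativeFracConc Beta model (mean,
#'   concentration) of the per-gene fraction of reads overlapping an
#'   informative SNP.
#' @slot geneLengthRange Log-uniform range of gene lengths (bp).
#' @slot seed Integer RNG seed.
#' @seealso [simulationConfig()], [simulateTriplets()]
#' @export
setClass("SimulationConfig",
  representation(
    nGenes = "integer", nReplicates = "integer", lines = "character",
    baselineLogMean = "numeric", baselineLogSd = "numeric",
    dispersion = "numeric", librarySizes = "numeric",
    fracDEG = "numeric", degLog2FC = "numeric",
    fracNonadditive = "numeric", nonadditiveModeMix = "numeric",
    nonadditiveLog2Deviation = "numeric", overdominanceMargin = "numeric",
    fracCisASE = "numeric", cisBias = "numeric",
    informativeFracMean = "numeric", informativeFracConc = "numeric",
    geneLengthRange = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  for (f in c("fracDEG", "fracNonadditive", "fracCisASE", "cisBias",
              "informativeFracMean")) {
    v <- slot(object, f)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      msgs <- c(msgs, paste0("'", f, "' must be in [0, 1]"))
    }
  }
  mix <- object@nonadditiveModeMix
  if (length(mix) != 4L || is.null(names(mix)) ||
      !setequal(names(mix), c("high_parent_dominance", "low_parent_dominance",
                              "over_dominance", "under_dominance"))) {
    msgs <- c(msgs, "'nonadditiveModeMix' must name the four modes")
  } else if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    msgs <- c(msgs, "'nonadditiveModeMix' must be non-negative and sum to 1")
  }
  if (any(object@dispersion <= 0)) {
    msgs <- c(msgs, "'dispersion' must be positive")
  }
  if (!all(is.na(object@librarySizes)) && any(object@librarySizes <= 0)) {
    msgs <- c(msgs, "'librarySizes' must be positive")
  }
  if (length(object@lines) < 2L) {
    msgs <- c(msgs, "at least two parent lines are required")
  }
  if (length(object@geneLengthRange) != 2L ||
      any(object@geneLengthRange <= 0) ||
      diff(object@geneLengthRange) < 0) {
    msgs <- c(msgs, "'geneLengthRange' must be an increasing positive pair")
  }
  if (length(msgs)) msgs else TRUE
})

#' SyntheticTriplets: a simulated triplet dataset with truth labels
#'
#' Container returned by [simulateTriplets()]: the simulated
#' [TripletCountSet-class], per-hybrid allelic counts, per-gene truth labels
#' (planted differential expression, non-additive pattern per hybrid,
#' cis-bias), the expected per-line means used to generate the data, and
#' the generating [SimulationConfig-class].
#'
#' @slot counts A [TripletCountSet-class].
#' @slot allelic A [S4Vectors::SimpleList] of per-hybrid `DataFrame`s with
#'   columns `gene_id`, `n1`, `n2` (parent-1/parent-2 allele informative
#'   reads, aggregated over the hybrid's replicates).
#' @slot truth Per-gene `DataFrame` of truth labels.
#' @slot expectedMeans Genes x lines matrix of expected relative expression.
#' @slot config The generating [SimulationConfig-class].
#' @seealso [simulateTriplets()], [truthLabels()], [allelicCounts()]
#' @export
setClass("SyntheticTriplets",
  representation(counts = "TripletCountSet", allelic = "SimpleList",
                 truth = "DataFrame", expectedMeans = "matrix",
                 config = "SimulationConfig"))

setValidity("SyntheticTriplets", function(object) {
  msgs <- character()
  if (nrow(object@truth) != nrow(object@counts)) {
    msgs <- c(msgs, "truth table must cover every gene exactly once")
  }
  cts <- assay(object@counts, "counts")
  cd <- colData(object@counts)
  for (h in names(object@allelic)) {
    al <- object@allelic[[h]]
    tot <- rowSums(cts[, cd$line == h, drop = FALSE])
    if (any(al$n1 + al$n2 > tot)) {
      msgs <- c(msgs, paste0("allelic reads exceed total reads in ", h))
    }
  }
  if (length(msgs)) msgs else TRUE
})
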