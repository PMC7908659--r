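#' Build a half-diallel triplet design
#'
#' Crosses every unordered pair of parents (no reciprocals, no
#' self-crosses); four parents give the six-hybrid "joint netted" design.
#'
#' @param parents Character vector of >= 2 parent line identifiers.
#' @param sep Separator used to form hybrid identifiers (`"T121xT126"`).
#' @return A [TripletDesign-class].
#' @examples
#' tripletDesign(c("T121", "T126", "PH4CV", "PH6WC"))
#' @export
tripletDesign <- function(parents, sep = "x") {
  parents <- as.character(parents)
  if (length(parents) < 2L) stop("need at least two parents")
  pairs <- utils::combn(parents, 2L)
  tr <- data.frame(parent1 = pairs[1L, ], parent2 = pairs[2L, ],
                   hybrid = paste(pairs[1L, ], pairs[2L, ], sep = sep),
                   stringsAsFactors = FALSE)
  new("TripletDesign", parents = parents, triplets = tr)
}

#' @rdname triplet-accessors
#' @export
setMethod("triplets", "TripletDesign", function(object) object@triplets)

#' @rdname triplet-accessors
#' @export
setMethod("parentLines", "TripletDesign", function(object) object@parents)

setMethod("show", "TripletDesign", function(object) {
  cat("TripletDesign:", length(object@parents), "parents,",
      nrow(object@triplets), "hybrids\n")
  cat("  parents:", paste(object@parents, collapse = ", "), "\n")
  cat("  hybrids:", paste(object@triplets$hybrid, collapse = ", "), "\n")
})

#' Triplets containing a focal parent
#'
#' @param design A [TripletDesign-class].
#' @param parent A parent line identifier.
#' @return The rows of `triplets(design)` whose cross involves `parent`.
#' @export
tripletsForParent <- function(design, parent) {
  stopifnot(is(design, "TripletDesign"))
  if (!parent %in% parentLines(design)) {
    stop("'", parent, "' is not a parent in this design")
  }
  tr <- triplets(design)
  tr[tr$parent1 == parent | tr$parent2 == parent, , drop = FALSE]
}

#' Intersect gene sets and count every Venn region
#'
#' @param sets Named list of >= 2 character vectors (gene sets; duplicates
#'   are removed).
#' @return A list with `intersection` (genes common to every set) and
#'   `regions`, a data.frame of all 2^k - 1 Venn region cardinalities
#'   (k <= 5), each region labelled by the sets it belongs to.
#' @examples
#' intersectSets(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' @export
intersectSets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L) {
    stop("'sets' must be a list of at least two gene sets")
  }
  if (length(sets) > 5L) stop("Venn region counts support at most 5 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0L) {
    member <- matrix(logical(0), 0L, length(sets),
                     dimnames = list(NULL, names(sets)))
  }
  if (is.vector(member)) member <- matrix(member, nrow = 1L)
  k <- length(sets)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1L, , drop = FALSE]
  colnames(patterns) <- names(sets)
  regionCount <- apply(patterns, 1L, function(p) {
    sum(apply(member, 1L, function(m) all(m == p)))
  })
  regions <- data.frame(
    region = apply(patterns, 1L, function(p) {
      paste(names(sets)[as.logical(p)], collapse = "&")
    }),
    n_sets = rowSums(patterns),
    count = regionCount,
    stringsAsFactors = FALSE)
  list(intersection = Reduce(intersect, sets), regions = regions)
}

#' Candidate genes for the additive effect of a focal parent pair
#'
#' Intersects the differential gene sets of two hybrid-vs-hybrid
#' comparisons (the two focal parents crossed to the same backgrounds) and
#' then the parent-vs-parent differential set, isolating genes whose
#' expression difference tracks the focal parent across backgrounds.
#'
#' @param degHybrids1,degHybrids2 Character vectors: differential genes
#'   between the corresponding hybrids in background 1 and 2.
#' @param degParents Character vector: differential genes between the two
#'   focal parents.
#' @return A list with `hybridOverlap` (the two hybrid comparisons'
#'   intersection) and `candidates` (that overlap intersected with the
#'   parental set).
#' @export
candidateAdditiveGenes <- function(degHybrids1, degHybrids2, degParents) {
  args <- list(degHybrids1 = degHybrids1, degHybrids2 = degHybrids2,
               degParents = degParents)
  for (nm in names(args)) {
    if (is.null(args[[nm]])) stop("missing comparison: '", nm, "'")
  }
  hybridOverlap <- intersect(unique(degHybrids1), unique(degHybrids2))
  list(hybridOverlap = hybridOverlap,
       candidates = intersect(hybridOverlap, unique(degParents)))
}

#' Candidate heterosis genes from non-additive sets of a focal parent
#'
#' For each focal parent, intersects the non-additive gene sets of the
#' three triplets containing it; with two focal parents, also returns the
#' genes shared by both intersections (non-additive in every hybrid of the
#' netted design).
#'
#' @param nonadditiveSets Named list of character vectors, one per hybrid
#'   (names are hybrid identifiers of `design`).
#' @param design A [TripletDesign-class].
#' @param focalParents One or two parent line identifiers.
#' @return A list with `perParent` (named list of 3-way intersections) and,
#'   for two focal parents, `shared`.
#' @export
candidateHeterosisGenes <- function(nonadditiveSets, design, focalParents) {
  stopifnot(is(design, "TripletDesign"))
  perParent <- lapply(focalParents, function(fp) {
    tr <- tripletsForParent(design, fp)
    if (nrow(tr) < 3L) {
      stop("focal parent '", fp, "' appears in fewer than 3 triplets")
    }
    miss <- setdiff(tr$hybrid, names(nonadditiveSets))
    if (length(miss)) {
      stop("missing non-additive sets for: ", paste(miss, collapse = ", "))
    }
    Reduce(intersect, lapply(nonadditiveSets[tr$hybrid], unique))
  })
  names(perParent) <- focalParents
  out <- list(perParent = perParent)
  if (length(focalParents) == 2L) {
    out$shared <- intersect(perParent[[1L]], perParent[[2L]])
  }
  out
}

#' Hypergeometric gene-set enrichment
#'
#' Annotation-agnostic over-representation test: for each term with K
#' annotated genes in a universe of N, the upper-tail hypergeometric
#' probability of observing >= k hits in a set of n genes,
#' P(X >= k) = `phyper(k - 1, K, N - K, n, lower.tail = FALSE)`.
#'
#' @param genes Character vector, the gene set (must be a subset of
#'   `universe`).
#' @param annotation Two-column data.frame mapping `gene` to `term`.
#' @param universe Character vector, the background gene universe.
#' @param alpha Raw p-value threshold used for the `significant` flag and
#'   the top-terms report (default 0.05).
#' @param top Number of top terms reported (default 10).
#' @return A list with `results` (all terms with K >= 1, ranked by p, with
#'   `k`, `K`, `n`, `N`, `p_value`, BH-adjusted `padj`, `rank`,
#'   `significant`) and `topTerms` (the `top` best terms with p < `alpha`).
#' @examples
#' ann <- data.frame(gene = paste0("g", 1:20),
#'                   term = rep(c("A", "B"), each = 10))
#' enrichGeneSet(paste0("g", 1:5), ann, paste0("g", 1:20))
#' @export
enrichGeneSet <- function(genes, annotation, universe, alpha = 0.05,
                          top = 10L) {
  genes <- unique(as.character(genes))
  universe <- unique(as.character(universe))
  if (!all(genes %in% universe)) {
    stop("'genes' must be a subset of 'universe'")
  }
  if (ncol(annotation) < 2L) {
    stop("'annotation' must have gene and term columns")
  }
  ann <- data.frame(gene = as.character(annotation[[1L]]),
                    term = as.character(annotation[[2L]]),
                    stringsAsFactors = FALSE)
  ann <- unique(ann[ann$gene %in% universe, , drop = FALSE])
  N <- length(universe)
  n <- length(genes)
  K <- table(ann$term)
  hits <- table(ann$term[ann$gene %in% genes])
  termIds <- names(K)[K >= 1L]      # terms absent from the universe skipped
  k <- as.integer(ifelse(termIds %in% names(hits), hits[termIds], 0L))
  Kv <- as.integer(K[termIds])
  p <- stats::phyper(k - 1L, Kv, N - Kv, n, lower.tail = FALSE)
  res <- data.frame(term_id = termIds, k = k, K = Kv, n = n, N = N,
                    p_value = p, stringsAsFactors = FALSE)
  res$padj <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res$significant <- res$p_value < alpha
  rownames(res) <- NULL
  list(results = res,
       topTerms = utils::head(res[res$significant, , drop = FALSE], top))
}
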