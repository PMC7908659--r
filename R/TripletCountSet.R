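#' Construct a TripletCountSet
#'
#' Bundles a gene x sample count matrix with per-sample line/replicate/role
#' metadata (and optionally the crossing design and gene lengths) into a
#' [TripletCountSet-class].
#'
#' @param counts Non-negative numeric matrix, genes as rows, samples as
#'   columns. Row names are gene identifiers.
#' @param line Character vector, one line identifier per sample.
#' @param replicate Vector of replicate labels per sample.
#' @param role Optional character vector, `"parent"` or `"hybrid"` per
#'   sample. Inferred from `design` when omitted.
#' @param design Optional [TripletDesign-class].
#' @param geneLengths Optional positive gene lengths (bp), recycled into
#'   `rowData`.
#' @return A [TripletCountSet-class].
#' @examples
#' cts <- matrix(rpois(40, 20), 10,
#'               dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' TripletCountSet(cts, line = c("A", "A", "B", "B"), replicate = c(1, 2, 1, 2),
#'                 role = rep("parent", 4))
#' @export
TripletCountSet <- function(counts, line, replicate, role = NULL,
                            design = NULL, geneLengths = NULL) {
  .assertCountMatrix(counts)
  if (length(line) != ncol(counts) || length(replicate) != ncol(counts)) {
    stop("'line' and 'replicate' must have one entry per sample")
  }
  if (is.null(role)) {
    if (is.null(design)) {
      stop("'role' is required when no 'design' is given")
    }
    role <- ifelse(line %in% parentLines(design), "parent", "hybrid")
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste(line, replicate, sep = "-")
  }
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(line = as.character(line),
                        replicate = as.character(replicate),
                        role = as.character(role),
                        row.names = colnames(counts)))
  if (!is.null(geneLengths)) {
    if (any(geneLengths <= 0)) stop("'geneLengths' must be positive")
    rowData(se)$gene_length <- rep_len(geneLengths, nrow(counts))
  }
  obj <- new("TripletCountSet", se)
  if (!is.null(design)) metadata(obj)$design <- design
  validObject(obj)
  obj
}

#' @describeIn TripletCountSet Count matrix accessor.
#' @param object A `TripletCountSet`.
#' @export
setMethod("counts", "TripletCountSet", function(object) {
  assay(object, "counts")
})

#' @rdname triplet-accessors
#' @export
setMethod("designOf", "TripletCountSet", function(object) {
  metadata(object)$design
})

#' Columns of a TripletCountSet belonging to one line
#'
#' @param object A [TripletCountSet-class].
#' @param line A line identifier present in `colData(object)$line`.
#' @return Count matrix restricted to that line's replicate columns.
#' @export
lineCounts <- function(object, line) {
  stopifnot(is(object, "TripletCountSet"))
  keep <- colData(object)$line == line
  if (!any(keep)) stop("no samples for line '", line, "'")
  counts(object)[, keep, drop = FALSE]
}

setMethod("show", "TripletCountSet", function(object) {
  cd <- colData(object)
  cat("TripletCountSet with", nrow(object), "genes,", ncol(object),
      "samples\n")
  cat("  lines:", paste(unique(cd$line), collapse = ", "), "\n")
  cat("  roles:", paste(sprintf("%s (%d)", names(table(cd$role)),
                                table(cd$role)), collapse = ", "), "\n")
})

setMethod("tripletCounts", "SyntheticTriplets", function(object) object@counts)
setMethod("allelicCounts", "SyntheticTriplets", function(object) {
  object@allelic
})
setMethod("truthLabels", "SyntheticTriplets", function(object) object@truth)
setMethod("designOf", "SyntheticTriplets", function(object) {
  designOf(object@counts)
})

#' @rdname triplet-accessors
#' @export
setMethod("counts", "SyntheticTriplets", function(object) {
  counts(object@counts)
})

#' Expected per-line relative expression means of a simulated dataset
#'
#' @param object A [SyntheticTriplets-class].
#' @return Genes x lines matrix of the generating expected means (relative
#'   scale, before library-size scaling).
#' @export
expectedMeans <- function(object) {
  stopifnot(is(object, "SyntheticTriplets"))
  object@expectedMeans
}

setMethod("show", "SyntheticTriplets", function(object) {
  cat("SyntheticTriplets:", nrow(object@truth), "genes\n")
  show(object@counts)
  tru <- object@truth
  cat("  planted: ", sum(tru$is_deg), " DEG, ",
      sum(tru$nonadditive_mode != "none"), " non-additive, ",
      sum(tru$is_cis_ase), " cis-ASE\n", sep = "")
})
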