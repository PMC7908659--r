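#' @importFrom BiocGenerics counts
NULL

#' Accessors for triplet objects
#'
#' `tripletCounts()` returns the [TripletCountSet-class]; `allelicCounts()`
#' the per-hybrid allelic count tables; `truthLabels()` the per-gene truth
#' table of a simulated dataset; `designOf()` the [TripletDesign-class];
#' `triplets()` its (parent1, parent2, hybrid) table; `parentLines()` its
#' parents.
#'
#' @param object A [SyntheticTriplets-class], [TripletCountSet-class] or
#'   [TripletDesign-class], as applicable.
#' @return The requested component.
#' @name triplet-accessors
#' @aliases tripletCounts allelicCounts truthLabels designOf triplets
#'   parentLines
NULL

#' @rdname triplet-accessors
#' @export
setGeneric("tripletCounts", function(object) standardGeneric("tripletCounts"))

#' @rdname triplet-accessors
#' @export
setGeneric("allelicCounts", function(object) standardGeneric("allelicCounts"))

#' @rdname triplet-accessors
#' @export
setGeneric("truthLabels", function(object) standardGeneric("truthLabels"))

#' @rdname triplet-accessors
#' @export
setGeneric("designOf", function(object) standardGeneric("designOf"))

#' @rdname triplet-accessors
#' @export
setGeneric("triplets", function(object) standardGeneric("triplets"))

#' @rdname triplet-accessors
#' @export
setGeneric("parentLines", function(object) standardGeneric("parentLines"))
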