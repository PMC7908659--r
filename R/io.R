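#' Read and write gene x sample count matrices as TSV
#'
#' Genes as rows (first column `gene_id`), samples as columns.
#'
#' @param path File path.
#' @return `readCountMatrix` returns a numeric matrix with gene row names.
#' @export
readCountMatrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "numeric"
  .assertCountMatrix(m)
  m
}

#' @rdname readCountMatrix
#' @param counts Matrix to write.
#' @export
writeCountMatrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `line`, `replicate`, `role`.
#'
#' @param path File path.
#' @return data.frame of the sheet.
#' @export
readSampleSheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "line", "replicate", "role")
  if (!all(need %in% colnames(sheet))) {
    stop("sample sheet must have columns ", paste(need, collapse = ", "))
  }
  sheet
}

#' Read a count matrix and sample sheet into a TripletCountSet
#'
#' @param countsPath,sheetPath Paths to the count matrix TSV and sample
#'   sheet TSV (samples matched by `sample_id` to count columns).
#' @param design Optional [TripletDesign-class].
#' @return A [TripletCountSet-class].
#' @export
readTripletCountSet <- function(countsPath, sheetPath, design = NULL) {
  m <- readCountMatrix(countsPath)
  sheet <- readSampleSheet(sheetPath)
  idx <- match(colnames(m), sheet$sample_id)
  if (any(is.na(idx))) {
    stop("count columns missing from sample sheet: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "))
  }
  sheet <- sheet[idx, , drop = FALSE]
  TripletCountSet(m, line = sheet$line, replicate = sheet$replicate,
                  role = sheet$role, design = design)
}

#' Read a gene set (one identifier per line)
#'
#' @param path File path.
#' @return Character vector of unique gene identifiers.
#' @export
readGeneSet <- function(path) {
  unique(scan(path, what = character(), quiet = TRUE, sep = "\n"))
}

#' Bundled ear-length phenotype summary
#'
#' Per-line means and standard deviations of young-ear (mm) and mature-ear
#' (cm) length for the four inbred parents and six hybrids of the maize
#' half-diallel study, with the published MPH percentages and LSD letters
#' for reference.
#'
#' @return data.frame with one row per line.
#' @export
earLengthTable <- function() {
  utils::read.delim(system.file("extdata", "ear_length_means.tsv",
                                package = "hetriplet"),
                    stringsAsFactors = FALSE)
}

#' Bundled per-library read statistics
#'
#' Raw, clean and uniquely mapped read counts for the study's 20 RNA-seq
#' libraries, with the published retention and mapped rates for reference.
#'
#' @return data.frame with one row per library.
#' @export
libraryReadStats <- function() {
  utils::read.delim(system.file("extdata", "library_read_stats.tsv",
                                package = "hetriplet"),
                    stringsAsFactors = FALSE)
}

#' Bundled parental-range gene counts
#'
#' Published within/out-of-parental-range gene counts per triplet over the
#' 25,199 expressed genes, with the published percentages for reference.
#'
#' @return data.frame with one row per triplet.
#' @export
parentalRangeCounts <- function() {
  utils::read.delim(system.file("extdata", "parental_range_counts.tsv",
                                package = "hetriplet"),
                    stringsAsFactors = FALSE)
}
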