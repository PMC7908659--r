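#' Configure a full triplet analysis run
#'
#' Validates and bundles everything [runPipeline()] needs: the simulation
#' config (or a pre-built dataset), the statistical thresholds, the stage
#' toggles, the master seed (fanned out deterministically to per-stage
#' child seeds) and an optional output directory for per-stage TSVs.
#'
#' @param simulation A [SimulationConfig-class]; its seed is overridden by
#'   the stage seed derived from `seed`.
#' @param pThreshold,lfcThreshold Joint differential criteria (defaults
#'   0.05, 1).
#' @param fdrThreshold ASE FDR threshold (default 0.05).
#' @param minDepth ASE depth filter (default 10).
#' @param permutations ASE Monte-Carlo permutations (default 1000).
#' @param seed Master seed (small integer).
#' @param focalParents Two parent lines whose additive/heterotic candidate
#'   sets are extracted (defaults to the first two lines of the design).
#' @param stages Character subset of `c("simulate", "qc", "deg",
#'   "patterns", "ase", "compare")`; later stages require earlier ones.
#' @param outDir Optional directory for TSV outputs.
#' @return A validated list of class `RunConfig`.
#' @export
runConfig <- function(simulation = simulationConfig(),
                      pThreshold = 0.05, lfcThreshold = 1,
                      fdrThreshold = 0.05, minDepth = 10,
                      permutations = 1000, seed = 1,
                      focalParents = NULL,
                      stages = c("simulate", "qc", "deg", "patterns",
                                 "ase", "compare"),
                      outDir = NULL) {
  stopifnot(is(simulation, "SimulationConfig"))
  if (pThreshold <= 0 || lfcThreshold <= 0 || fdrThreshold <= 0 ||
      minDepth < 1 || permutations < 1) {
    stop("thresholds must be positive")
  }
  allStages <- c("simulate", "qc", "deg", "patterns", "ase", "compare")
  stages <- match.arg(stages, allStages, several.ok = TRUE)
  need <- list(qc = "simulate", deg = "simulate", patterns = "deg",
               ase = "simulate", compare = c("deg", "patterns"))
  for (s in stages) {
    miss <- setdiff(need[[s]], stages)
    if (length(miss)) {
      stop("stage '", s, "' requires stage(s): ", paste(miss, collapse = ", "))
    }
  }
  if (is.null(focalParents)) focalParents <- simulation@lines[1:2]
  if (!all(focalParents %in% simulation@lines) ||
      length(focalParents) != 2L) {
    stop("'focalParents' must name two parent lines of the design")
  }
  structure(list(simulation = simulation, pThreshold = pThreshold,
                 lfcThreshold = lfcThreshold, fdrThreshold = fdrThreshold,
                 minDepth = minDepth, permutations = permutations,
                 seed = as.integer(seed), focalParents = focalParents,
                 stages = stages, outDir = outDir),
            class = "RunConfig")
}

# deterministic per-stage child seeds from the master seed, kept inside
# 32-bit integer range
.stageSeed <- function(seed, stage) {
  offsets <- c(simulate = 101L, ase = 211L, other = 307L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else offsets[["other"]]
  as.integer((as.numeric(seed) * 7919 + off) %% .Machine$integer.max)
}

#' Run the full triplet heterosis analysis
#'
#' Executes the enabled stages in dependency order on a simulated dataset:
#' count simulation, library QC and size factors, differential expression
#' for every parent-parent and hybrid-parent pair, non-additive pattern
#' classification and parental-range summaries per triplet, permutation
#' ASE calling per hybrid, and the multi-triplet candidate-set
#' comparisons. Identical config and seed reproduce every table exactly.
#'
#' @param config A `RunConfig` from [runConfig()].
#' @return A list of class `tripletRun` with (by stage) `data`,
#'   `qc`, `deg`, `patterns`, `range`, `ase`, `compare`, and `report`
#'   (summary tables whose percentages are arithmetic over the reported
#'   numerators/denominators). Written as TSVs under `config$outDir` when
#'   set.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "RunConfig")) stop("'config' must come from runConfig()")
  res <- list(config = config)
  stages <- config$stages

  simCfg <- config$simulation
  simCfg@seed <- .stageSeed(config$seed, "simulate")
  sim <- simulateTriplets(simCfg)
  res$data <- sim
  tcs <- tripletCounts(sim)
  design <- designOf(tcs)
  tr <- triplets(design)
  cd <- colData(tcs)
  cts <- counts(tcs)

  if ("qc" %in% stages) {
    tot <- colSums(cts)
    res$qc <- list(
      libraries = summarizeLibraryQC(raw = tot, clean = tot, mapped = tot,
                                     sample_id = colnames(cts)),
      size_factors = sizeFactorsMedianRatios(cts),
      replicate_correlation = vapply(unique(cd$line), function(l) {
        replicateCorrelation(tcs, l)
      }, numeric(1L)))
  }

  sf <- sizeFactorsMedianRatios(cts)
  norm <- normalizeCounts(cts, sf)
  lineCols <- function(l) norm[, cd$line == l, drop = FALSE]

  if ("deg" %in% stages) {
    comparisons <- rbind(
      data.frame(a = tr$parent1, b = tr$parent2),
      data.frame(a = tr$hybrid, b = tr$parent1),
      data.frame(a = tr$hybrid, b = tr$parent2))
    comparisons <- unique(comparisons)
    deg <- lapply(seq_len(nrow(comparisons)), function(i) {
      testDifferential(lineCols(comparisons$a[i]), lineCols(comparisons$b[i]),
                       pThreshold = config$pThreshold,
                       lfcThreshold = config$lfcThreshold)
    })
    names(deg) <- paste(comparisons$a, "vs", comparisons$b)
    res$deg <- deg
  }

  if ("patterns" %in% stages) {
    res$patterns <- lapply(seq_len(nrow(tr)), function(i) {
      h <- lineCols(tr$hybrid[i])
      p1 <- lineCols(tr$parent1[i])
      p2 <- lineCols(tr$parent2[i])
      # columns are already globally normalized, so triplet factors are 1
      classifyPatterns(h, p1, p2,
                       sizeFactors = rep(1, ncol(h) + ncol(p1) + ncol(p2)),
                       pThreshold = config$pThreshold,
                       lfcThreshold = config$lfcThreshold)
    })
    names(res$patterns) <- tr$hybrid
    lineMeans <- averageReplicates(norm, cd$line)
    res$range <- lapply(seq_len(nrow(tr)), function(i) {
      classifyParentalRange(lineMeans[, tr$parent1[i]],
                            lineMeans[, tr$parent2[i]],
                            lineMeans[, tr$hybrid[i]])$summary
    })
    names(res$range) <- tr$hybrid
  }

  if ("ase" %in% stages) {
    aseSeed <- .stageSeed(config$seed, "ase")
    res$ase <- lapply(seq_along(allelicCounts(sim)), function(i) {
      callASE(as.data.frame(allelicCounts(sim)[[i]]),
              B = config$permutations, minDepth = config$minDepth,
              seed = aseSeed + i, fdrThreshold = config$fdrThreshold)
    })
    names(res$ase) <- names(allelicCounts(sim))
  }

  if ("compare" %in% stages) {
    fp <- config$focalParents
    others <- setdiff(parentLines(design), fp)
    hyb <- function(a, b) {
      tr$hybrid[(tr$parent1 == a & tr$parent2 == b) |
                (tr$parent1 == b & tr$parent2 == a)]
    }
    degSet <- function(nm) {
      r <- res$deg[[nm]]
      r$gene_id[r$isDEG]
    }
    pairName <- function(a, b) {
      nm <- paste(a, "vs", b)
      if (nm %in% names(res$deg)) nm else paste(b, "vs", a)
    }
    degBetween <- function(a, b) degSet(pairName(a, b))
    hvh <- lapply(others, function(bg) {
      testDifferential(lineCols(hyb(fp[1L], bg)), lineCols(hyb(fp[2L], bg)),
                       pThreshold = config$pThreshold,
                       lfcThreshold = config$lfcThreshold)
    })
    names(hvh) <- paste0(vapply(others, function(bg) hyb(fp[1L], bg), ""),
                         " vs ",
                         vapply(others, function(bg) hyb(fp[2L], bg), ""))
    naSets <- lapply(res$patterns, function(p) p$gene_id[p$nonadditive])
    res$compare <- list(
      hybrid_vs_hybrid = hvh,
      additive_candidates = candidateAdditiveGenes(
        hvh[[1L]]$gene_id[hvh[[1L]]$isDEG],
        hvh[[2L]]$gene_id[hvh[[2L]]$isDEG],
        degBetween(fp[1L], fp[2L])),
      heterosis_candidates = candidateHeterosisGenes(naSets, design, fp))
  }

  res$report <- .runReport(res)
  if (!is.null(config$outDir)) .writeRun(res, config$outDir)
  class(res) <- "tripletRun"
  res
}

.runReport <- function(res) {
  rep <- list(seed = res$config$seed,
              parameters = res$config[c("pThreshold", "lfcThreshold",
                                        "fdrThreshold", "minDepth",
                                        "permutations")],
              package_version = as.character(utils::packageVersion("hetriplet")))
  if (!is.null(res$deg)) {
    rep$deg_counts <- data.frame(
      comparison = names(res$deg),
      n_deg = vapply(res$deg, function(r) sum(r$isDEG), integer(1L)),
      row.names = NULL)
  }
  if (!is.null(res$patterns)) {
    rep$nonadditive_counts <- data.frame(
      hybrid = names(res$patterns),
      n_nonadditive = vapply(res$patterns, function(p) sum(p$nonadditive),
                             integer(1L)),
      n_tested = vapply(res$patterns, nrow, integer(1L)),
      row.names = NULL)
    rep$range_summary <- do.call(rbind, c(res$range, make.row.names = FALSE))
    rep$range_summary$hybrid <- names(res$range)
  }
  if (!is.null(res$ase)) {
    rep$ase_counts <- data.frame(
      hybrid = names(res$ase),
      n_tested = vapply(res$ase, function(a) sum(a$tested), integer(1L)),
      n_ase = vapply(res$ase, function(a) sum(a$is_ase), integer(1L)),
      row.names = NULL)
  }
  if (!is.null(res$compare)) {
    rep$candidate_counts <- data.frame(
      set = c("hybrid_overlap", "additive_candidates",
              paste0("heterosis_", names(res$compare$heterosis_candidates$perParent)),
              "heterosis_shared"),
      n = c(length(res$compare$additive_candidates$hybridOverlap),
            length(res$compare$additive_candidates$candidates),
            vapply(res$compare$heterosis_candidates$perParent, length,
                   integer(1L)),
            length(res$compare$heterosis_candidates$shared)),
      row.names = NULL)
  }
  rep
}

.writeRun <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTriplets(res$data, file.path(dir, "simulated"))
  wt <- function(x, name) {
    utils::write.table(as.data.frame(x), file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$qc)) wt(res$qc$libraries, "library_qc.tsv")
  for (nm in names(res$deg)) {
    wt(res$deg[[nm]], paste0("deg_", gsub(" ", "_", nm), ".tsv"))
  }
  for (nm in names(res$patterns)) {
    wt(res$patterns[[nm]], paste0("patterns_", nm, ".tsv"))
  }
  for (nm in names(res$ase)) wt(res$ase[[nm]], paste0("ase_", nm, ".tsv"))
  for (nm in c("deg_counts", "nonadditive_counts", "range_summary",
               "ase_counts", "candidate_counts")) {
    if (!is.null(res$report[[nm]])) wt(res$report[[nm]],
                                       paste0("report_", nm, ".tsv"))
  }
  invisible(dir)
}

#' @export
print.tripletRun <- function(x, ...) {
  cat("tripletRun (seed ", x$config$seed, ")\n", sep = "")
  cat("  stages:", paste(x$config$stages, collapse = ", "), "\n")
  if (!is.null(x$report$deg_counts)) {
    cat("  DEG comparisons:", nrow(x$report$deg_counts), "\n")
  }
  if (!is.null(x$report$nonadditive_counts)) {
    cat("  non-additive per hybrid:",
        paste(x$report$nonadditive_counts$n_nonadditive, collapse = ", "),
        "\n")
  }
  if (!is.null(x$report$ase_counts)) {
    cat("  ASE per hybrid:",
        paste(x$report$ase_counts$n_ase, collapse = ", "), "\n")
  }
  invisible(x)
}
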