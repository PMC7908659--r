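# Small deterministic fixtures shared across tests.

smallSimConfig <- function(...) {
  # 4-parent half-diallel, scaled down so every stage runs in milliseconds
  defaults <- list(nGenes = 300, librarySizes = 3e4, seed = 11)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulationConfig, args)
}

# counts with exact per-column values, as a genes x samples matrix
constantCounts <- function(values, nrep = 2, genes = NULL) {
  m <- matrix(rep(values, times = nrep), nrow = length(values), ncol = nrep)
  rownames(m) <- if (is.null(genes)) paste0("g", seq_along(values)) else genes
  m
}

nullMix <- c(high_parent_dominance = 0.25, low_parent_dominance = 0.25,
             over_dominance = 0.25, under_dominance = 0.25)
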