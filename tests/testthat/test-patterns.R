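test_that("mid-parent pseudo-samples are paired rounded means", {
  p <- matrix(c(10, 50), 1)
  expect_equal(buildMidparentPseudosamples(p, p), p, ignore_attr = TRUE)
  expect_equal(
    buildMidparentPseudosamples(matrix(10, 1, 2), matrix(30, 1, 2)),
    matrix(20, 1, 2), ignore_attr = TRUE)
  set.seed(2)
  a <- matrix(rnbinom(100, mu = 40, size = 5), 50)
  b <- matrix(rnbinom(100, mu = 40, size = 5), 50)
  expect_equal(buildMidparentPseudosamples(a, b), round((a + b) / 2),
               ignore_attr = TRUE)
  expect_error(buildMidparentPseudosamples(a, b[, 1, drop = FALSE]),
               "recycled")
})

test_that("a hybrid numerically at mid-parent yields zero non-additive calls", {
  set.seed(14)
  p1 <- matrix(rnbinom(400, mu = 200, size = 10), 200)
  p2 <- matrix(rnbinom(400, mu = 200, size = 10), 200)
  hybrid <- round((p1 + p2) / 2)   # exactly the MP pseudo-samples
  res <- callNonadditive(hybrid, p1, p2, sizeFactors = rep(1, 6))
  expect_identical(sum(res$nonadditive), 0L)
})

test_that("null triplets keep the non-additive rate near the joint-criteria floor", {
  cfg <- simulationConfig(nGenes = 3000, librarySizes = 3000 * 50,
                          fracDEG = 0, fracNonadditive = 0, fracCisASE = 0,
                          seed = 41)
  sim <- simulateTriplets(cfg)
  tcs <- tripletCounts(sim)
  cd <- SummarizedExperiment::colData(tcs)
  tr <- triplets(designOf(sim))[1, ]
  cts <- counts(tcs)
  res <- callNonadditive(cts[, cd$line == tr$hybrid],
                         cts[, cd$line == tr$parent1],
                         cts[, cd$line == tr$parent2])
  # the joint p < 0.05 & |lfc| > 1 criteria call far fewer than 5% under null
  expect_lt(mean(res$nonadditive), 0.05)
})

test_that("planted over/under-dominant genes are recalled and classified", {
  mix <- c(high_parent_dominance = 0, low_parent_dominance = 0,
           over_dominance = 0.5, under_dominance = 0.5)
  cfg <- simulationConfig(nGenes = 3000, librarySizes = 3000 * 50,
                          fracDEG = 0, fracNonadditive = 0.1,
                          nonadditiveModeMix = mix,
                          nonadditiveLog2Deviation = 2, fracCisASE = 0,
                          seed = 43)
  sim <- simulateTriplets(cfg)
  tru <- truthLabels(sim)
  tcs <- tripletCounts(sim)
  cd <- SummarizedExperiment::colData(tcs)
  tr <- triplets(designOf(sim))[1, ]
  cts <- counts(tcs)
  pat <- classifyPatterns(cts[, cd$line == tr$hybrid],
                          cts[, cd$line == tr$parent1],
                          cts[, cd$line == tr$parent2])
  planted <- tru[[paste0("pattern_", tr$hybrid)]]
  overIdx <- planted == "over_dominance"
  underIdx <- planted == "under_dominance"
  expect_gt(mean(pat$nonadditive[overIdx | underIdx]), 0.5)
  called <- pat$pattern[overIdx & pat$nonadditive]
  expect_gt(mean(called == "over_dominance"), 0.8)
  calledU <- pat$pattern[underIdx & pat$nonadditive]
  expect_gt(mean(calledU == "under_dominance"), 0.8)
  # null genes overwhelmingly additive
  expect_gt(mean(pat$pattern[planted == "additive"] == "additive"), 0.9)
})

test_that("dominance labels are reachable for partial-dominance hybrids", {
  # hybrid above the high parent but within its significance band, parents
  # far apart: significantly off MP, indistinguishable from the high parent
  set.seed(51)
  n <- 200
  lo <- matrix(rnbinom(2 * n, mu = 50, size = 50), n)
  hi <- matrix(rnbinom(2 * n, mu = 500, size = 50), n)
  hyb <- matrix(rnbinom(2 * n, mu = 520, size = 50), n)
  pat <- classifyPatterns(hyb, hi, lo, sizeFactors = rep(1, 6))
  called <- table(pat$pattern[pat$nonadditive])
  expect_gt(called[["high_parent_dominance"]],
            0.8 * sum(pat$nonadditive))
})

test_that("pattern labels ignore the order the parents are given in", {
  sim <- simulateTriplets(smallSimConfig(fracNonadditive = 0.2, seed = 45))
  tcs <- tripletCounts(sim)
  cd <- SummarizedExperiment::colData(tcs)
  tr <- triplets(designOf(sim))[2, ]
  cts <- counts(tcs)
  a <- classifyPatterns(cts[, cd$line == tr$hybrid],
                        cts[, cd$line == tr$parent1],
                        cts[, cd$line == tr$parent2])
  b <- classifyPatterns(cts[, cd$line == tr$hybrid],
                        cts[, cd$line == tr$parent2],
                        cts[, cd$line == tr$parent1])
  expect_identical(as.character(a$pattern), as.character(b$pattern))
  expect_identical(a$withinParentalRange, b$withinParentalRange)
})

test_that("additive and non-additive partition the tested genes", {
  sim <- simulateTriplets(smallSimConfig(fracNonadditive = 0.2, seed = 47))
  tcs <- tripletCounts(sim)
  cd <- SummarizedExperiment::colData(tcs)
  tr <- triplets(designOf(sim))[1, ]
  cts <- counts(tcs)
  pat <- classifyPatterns(cts[, cd$line == tr$hybrid],
                          cts[, cd$line == tr$parent1],
                          cts[, cd$line == tr$parent2])
  expect_identical(sum(pat$pattern == "additive") + sum(pat$nonadditive),
                   nrow(pat))
})

test_that("parental-range classification uses inclusive bounds", {
  res <- classifyParentalRange(c(10, 10, 10), c(20, 20, 20), c(10, 25, 15))
  expect_identical(res$within, c(TRUE, FALSE, TRUE))
  s <- res$summary
  expect_equal(s$within_pct + s$out_pct, 100, tolerance = 0.011)

  printed <- rangeSummary(16371, 8828)
  expect_equal(printed$within_pct, 64.97)
  expect_equal(printed$out_pct, 35.03)
  expect_identical(printed$total, 25199)
})
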