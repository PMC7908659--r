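test_that("library QC reproduces printed per-library rates", {
  qc <- summarizeLibraryQC(13871140, 13443019, 11622834)
  expect_equal(qc$retention_rate, 96.91)
  expect_equal(qc$mapped_rate, 86.46)
  qc2 <- summarizeLibraryQC(14658208, 13170436, 10408596)
  expect_equal(qc2$retention_rate, 89.85)
  expect_equal(qc2$mapped_rate, 79.03)
  idem <- summarizeLibraryQC(5e6, 5e6, 5e6)
  expect_equal(idem$retention_rate, 100)
  expect_equal(idem$mapped_rate, 100)
})

test_that("library QC rejects impossible or degenerate inputs", {
  expect_error(summarizeLibraryQC(0, 0, 0), "undefined")
  expect_error(summarizeLibraryQC(100, 0, 0), "undefined")
  expect_error(summarizeLibraryQC(100, 120, 90), "clean <= raw")
  expect_error(summarizeLibraryQC(100, 90, 95), "mapped <= clean")
})

test_that("median-of-ratios size factors match analytic and brute-force values", {
  m <- constantCounts(c(10, 20, 30), nrep = 2)
  expect_equal(unname(sizeFactorsMedianRatios(m)), c(1, 1))

  twoFold <- cbind(a = c(10, 20, 40), b = c(20, 40, 80))
  expect_equal(unname(sizeFactorsMedianRatios(twoFold)),
               c(1 / sqrt(2), sqrt(2)))

  set.seed(21)
  r <- matrix(rnbinom(500 * 5, mu = 60, size = 5), 500)
  sf <- sizeFactorsMedianRatios(r)
  # brute-force oracle: literal geometric mean and median-of-ratios loops
  pos <- apply(r, 1, function(x) all(x > 0))
  ref <- apply(r[pos, ], 1, function(x) prod(x)^(1 / length(x)))
  oracle <- vapply(seq_len(ncol(r)), function(j) {
    median(r[pos, j] / ref)
  }, numeric(1))
  expect_equal(unname(sf), oracle, tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(33)
  r <- matrix(rnbinom(400 * 6, mu = 80, size = 8), 400)
  # DESeq2 interpolates the even-count median on the log scale, this
  # implementation on the ratio scale, so agreement is near- but not
  # to-machine-exact
  expect_equal(unname(sizeFactorsMedianRatios(r)),
               unname(DESeq2::estimateSizeFactorsForMatrix(r)),
               tolerance = 1e-4)
})

test_that("size factors are scale-equivariant and fail without a reference", {
  set.seed(8)
  r <- matrix(rnbinom(300 * 4, mu = 50, size = 10) + 1, 300)
  sf <- sizeFactorsMedianRatios(r)
  r2 <- r
  r2[, 2] <- r2[, 2] * 3
  sf2 <- sizeFactorsMedianRatios(r2)
  # factors are defined up to a common scale: scaling one sample by c
  # scales its factor by c relative to the others
  expect_equal(sf2[2] / sf2[1], 3 * sf[2] / sf[1], tolerance = 1e-12,
               ignore_attr = TRUE)

  noRef <- rbind(c(0, 5), c(5, 0))
  expect_error(sizeFactorsMedianRatios(noRef), "pseudo-reference")
})

test_that("FPKM matches its formula", {
  expect_equal(computeFPKM(matrix(10), geneLengths = 1000,
                           mappedTotals = 1e6)[1, 1], 10)
  expect_equal(computeFPKM(matrix(0), geneLengths = 1000,
                           mappedTotals = 1e6)[1, 1], 0)
  set.seed(4)
  cts <- matrix(rpois(60, 40), 20)
  len <- sample(500:5000, 20)
  tot <- colSums(cts)
  got <- computeFPKM(cts, len, tot)
  want <- cts
  for (g in 1:20) for (j in 1:3) {
    want[g, j] <- cts[g, j] * 1e9 / (len[g] * tot[j])
  }
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(computeFPKM(matrix(1), geneLengths = 0, mappedTotals = 1),
               "positive")
})

test_that("FPKM is preserved when counts split across equal-length genes", {
  cts <- matrix(c(100, 0), 2, 1)
  split <- matrix(c(60, 40), 2, 1)
  len <- c(2000, 2000)
  tot <- 1e6
  expect_equal(sum(computeFPKM(cts, len, tot)),
               sum(computeFPKM(split, len, tot)), tolerance = 1e-12)
})

test_that("replicate correlation behaves on identical, scaled and simulated pairs", {
  set.seed(12)
  x <- rnbinom(500, mu = 100, size = 5) + 1   # no zeros
  expect_equal(replicateCorrelation(cbind(x, x)), 1)

  # scaling is absorbed by normalization before the correlation
  m <- cbind(x, 2 * x)
  sf <- sizeFactorsMedianRatios(m)
  expect_equal(replicateCorrelation(normalizeCounts(m, sf)), 1,
               tolerance = 1e-12)

  sim <- simulateTriplets(simulationConfig(nGenes = 2000, librarySizes = 2e6,
                                           seed = 2))
  expect_gt(replicateCorrelation(tripletCounts(sim), "T121"), 0.9)

  expect_error(replicateCorrelation(cbind(rep(1, 5), rnorm(5) + 2)),
               "constant")
})

test_that("replicate averaging is the arithmetic per-line mean", {
  m <- cbind(a1 = c(2, 10), a2 = c(4, 14), b1 = c(6, 0), b2 = c(8, 2))
  got <- averageReplicates(m, c("a", "a", "b", "b"))
  expect_equal(got[, "a"], c(3, 12), ignore_attr = TRUE)
  expect_equal(got[, "b"], c(7, 1), ignore_attr = TRUE)
  set.seed(3)
  r <- matrix(rnorm(40, 50), 10)
  lines <- c("x", "y", "x", "y")
  got <- averageReplicates(r, lines)
  expect_equal(got[, "x"], rowMeans(r[, c(1, 3)]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(averageReplicates(r, c("x", "y")), "one line per column")
})
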