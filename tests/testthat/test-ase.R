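test_that("read assignment follows the all-or-nothing SNP match rule", {
  pr <- data.frame(
    read_id = c("r1", "r1", "r1", "r2", "r3", "r3", "r3", "r4", "r5"),
    gene_id = c(rep("g1", 3), "g1", rep("g2", 3), "g2", "g3"),
    observed = c("A", "C", "G", "T", "A", "C", "T", "A", "A"),
    allele1  = c("A", "C", "G", "T", "A", "C", "G", "A", "A"),
    allele2  = c("T", "G", "A", "T", "T", "G", "T", "A", "C"),
    stringsAsFactors = FALSE)
  got <- assignReads(pr)
  got <- got[order(got$read_id), ]
  # r1: 3 informative SNPs all parent1; r2: no informative SNP (equal
  # alleles); r3: 2 parent1 + 1 parent2 -> conflicting; r4: only a
  # non-informative SNP -> ambiguous; r5: single parent1 SNP
  expect_identical(got$assignment,
                   c("parent1", "ambiguous", "conflicting", "ambiguous",
                     "parent1"))
  # a base matching neither allele also conflicts
  odd <- data.frame(read_id = "rx", gene_id = "g", observed = "N",
                    allele1 = "A", allele2 = "C")
  expect_identical(assignReads(odd)$assignment, "conflicting")
})

test_that("allelic aggregation tallies assigned reads only", {
  asg <- data.frame(
    gene_id = c(rep("g1", 18), rep("g2", 2)),
    assignment = c(rep("parent1", 10), rep("parent2", 5),
                   rep("ambiguous", 3), "parent1", "conflicting"))
  got <- aggregateAllelicCounts(asg)
  expect_identical(got$n1[got$gene_id == "g1"], 10L)
  expect_identical(got$n2[got$gene_id == "g1"], 5L)
  expect_identical(got$n1[got$gene_id == "g2"], 1L)
  empty <- aggregateAllelicCounts(asg, genes = c("g1", "g2", "g3"))
  expect_identical(empty$n1[empty$gene_id == "g3"], 0L)

  set.seed(6)
  stream <- data.frame(
    gene_id = sample(paste0("g", 1:20), 500, replace = TRUE),
    assignment = sample(c("parent1", "parent2", "ambiguous", "conflicting"),
                        500, replace = TRUE))
  got <- aggregateAllelicCounts(stream, genes = paste0("g", 1:20))
  for (g in paste0("g", 1:20)) {
    expect_identical(got$n1[got$gene_id == g],
                     sum(stream$gene_id == g & stream$assignment == "parent1"))
  }
})

test_that("perfect balance and total imbalance hit the p-value extremes", {
  # fillers are bias-symmetric so the two-column size factors stay at 1
  tab <- data.frame(gene_id = c("balanced", "extreme", paste0("f", 1:20)),
                    n1 = c(50, 100, rep(c(60, 40), 10)),
                    n2 = c(50, 0, rep(c(40, 60), 10)))
  res <- callASE(tab, B = 1000, seed = 3)
  expect_equal(res$perm_p[res$gene_id == "balanced"], 1)
  expect_false(res$is_ase[res$gene_id == "balanced"])
  expect_equal(res$perm_p[res$gene_id == "extreme"], 1 / 1001)
  expect_true(res$is_ase[res$gene_id == "extreme"])
  expect_identical(res$biased_parent[res$gene_id == "extreme"], "parent1")
})

test_that("permutation p-values live on the attainable grid, reproducibly", {
  set.seed(9)
  tab <- data.frame(gene_id = paste0("g", 1:200),
                    n1 = rbinom(200, 100, 0.5))
  tab$n2 <- 100 - tab$n1
  r1 <- callASE(tab, B = 500, seed = 17)
  r2 <- callASE(tab, B = 500, seed = 17)
  expect_identical(r1, r2)
  grid <- seq_len(501) / 501
  expect_true(all(r1$perm_p[r1$tested] %in% grid))
  expect_true(all(r1$perm_p[r1$tested] >= 1 / 501))
  # swapping the allele columns leaves the statistic, hence p, unchanged
  swapped <- callASE(data.frame(gene_id = tab$gene_id, n1 = tab$n2,
                                n2 = tab$n1), B = 500, seed = 17)
  expect_equal(swapped$perm_p, r1$perm_p)
})

test_that("shallow genes are untested rather than silently p = 1", {
  tab <- data.frame(gene_id = c("deep", "shallow"), n1 = c(30, 3),
                    n2 = c(30, 2))
  res <- callASE(tab, B = 100, minDepth = 10, seed = 1)
  expect_true(is.na(res$perm_p[res$gene_id == "shallow"]))
  expect_false(res$tested[res$gene_id == "shallow"])
  expect_false(res$is_ase[res$gene_id == "shallow"])
})

test_that("permutation p agrees with the exact binomial test", {
  set.seed(29)
  n <- 1000
  # null genes: their exact p-values stay above the 1/(B+1) floor, so the
  # Monte-Carlo and exact tests rank genes on comparable support (strongly
  # biased genes would all saturate the floor and tie)
  tab <- data.frame(gene_id = paste0("g", seq_len(n)),
                    n1 = rbinom(n, 100, 0.5))
  tab$n2 <- 100 - tab$n1
  res <- callASE(tab, B = 1000, seed = 31)
  exact <- vapply(seq_len(n), function(i) {
    stats::binom.test(tab$n1[i], 100, 0.5)$p.value
  }, numeric(1))
  expect_gt(cor(res$perm_p, exact, method = "spearman"), 0.99)
})

test_that("BH ordering and the FDR threshold are respected exactly", {
  set.seed(35)
  tab <- data.frame(gene_id = paste0("g", 1:300),
                    n1 = c(rbinom(250, 100, 0.5), rbinom(50, 100, 0.85)))
  tab$n2 <- 100 - tab$n1
  res <- callASE(tab, B = 1000, seed = 37)
  tested <- res[res$tested, ]
  ord <- order(tested$perm_p)
  expect_true(all(diff(tested$fdr_q[ord]) >= -1e-12))
  expect_identical(res$is_ase, !is.na(res$fdr_q) & res$fdr_q < 0.05)
  expect_equal(tested$fdr_q,
               p.adjust(tested$perm_p, method = "BH"))
})

test_that("power rises with the planted allelic bias", {
  powerAt <- function(p, seed) {
    set.seed(seed)
    tab <- data.frame(gene_id = paste0("g", 1:400),
                      n1 = c(rbinom(200, 100, 0.5), rbinom(200, 100, p)))
    tab$n2 <- 100 - tab$n1
    res <- callASE(tab, B = 1000, seed = seed + 1)
    mean(res$is_ase[201:400])
  }
  expect_gt(powerAt(0.9, 53), powerAt(0.6, 53))
})

test_that("independently planted ASE and non-additive labels barely overlap", {
  sim <- simulateTriplets(smallSimConfig(nGenes = 2000, librarySizes = 2e5,
                                         fracNonadditive = 0.1,
                                         fracCisASE = 0.1, seed = 57))
  tru <- truthLabels(sim)
  both <- sum(tru$is_cis_ase & tru$nonadditive_mode != "none")
  # independence-level overlap: ~ nGenes * 0.1 * 0.1 = 20
  expect_lt(both, 45)
})

test_that("SNP tables read from TSV and VCF with 0-based conversion", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tparent1_allele\tparent2_allele\tgene_id",
               "chr1\t99\tA\tG\tg1", "chr1\t150\tC\tC\tg1"), tsv)
  snp <- readSnpTable(tsv)
  expect_identical(snp$informative, c(TRUE, FALSE))

  skip_if_not_installed("vcfR")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tA\tG\t.\tPASS\t.",
               "chr1\t200\t.\tC\tT,A\t.\tPASS\t.",
               "chr1\t300\t.\tGA\tG\t.\tPASS\t.",
               "chr1\t5000\t.\tT\tC\t.\tPASS\t."), vcf)
  genes <- data.frame(chrom = "chr1", start = 50, end = 400, gene_id = "g1")
  got <- readSnpVcf(vcf, genes)
  # multi-allelic and indel records dropped; SNP outside the gene dropped
  expect_identical(nrow(got), 1L)
  expect_identical(got$pos, 99L)   # 1-based 100 -> 0-based 99
  expect_identical(got$gene_id, "g1")
})
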