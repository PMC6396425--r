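fixtureAnnotation <- function() {
  geneAnnotation(
    gene_id = sprintf("G%d", 1:6),
    tss = c(5500L, 20500L, 40500L, 60500L, 80500L, 90500L),
    promoter_start = c(5000L, 20000L, 40000L, 60000L, 80000L, 90000L),
    promoter_end = c(6000L, 21000L, 41000L, 61000L, 81000L, 91000L),
    bait_start = c(4000L, 19000L, 39000L, NA, NA, NA),
    bait_end = c(7000L, 22000L, 42000L, NA, NA, NA))
}

emptyPairTable <- function() {
  data.table::data.table(pos_i = integer(), pos_j = integer(),
                         r2 = numeric(), dprime = numeric(),
                         distance = integer(), population = character())
}

test_that("gene annotation validates promoter-TSS containment", {
  expect_error(geneAnnotation("G1", tss = 100L, promoter_start = 200L,
                              promoter_end = 300L), "contain the TSS")
  expect_error(geneAnnotation(c("G1", "G1"), tss = c(100L, 100L),
                              promoter_start = c(50L, 50L),
                              promoter_end = c(150L, 150L)), "unique")
})

test_that("feature vectors implement the PIR/bait eQTL definition", {
  ann <- fixtureAnnotation()
  # interaction: bait = G1 fragment [4000, 7000), PIR = [50000, 55000)
  tr <- InteractionTrack("chrS", 4000, 7000, 50000, 55000, score = 6)
  # eQTL SNP inside the PIR targeting G1 -> has_eqtl TRUE
  fv <- interactionFeatureVectors(
    tr, data.frame(snp_pos = 52000L, gene_id = "G1"), ann,
    emptyPairTable())
  expect_true(fv$has_eqtl)
  # eQTL SNP in the bait (not the PIR) -> FALSE
  fv2 <- interactionFeatureVectors(
    tr, data.frame(snp_pos = 5000L, gene_id = "G1"), ann,
    emptyPairTable())
  expect_false(fv2$has_eqtl)
  # eQTL in PIR but targeting a different bait -> FALSE
  fv3 <- interactionFeatureVectors(
    tr, data.frame(snp_pos = 52000L, gene_id = "G2"), ann,
    emptyPairTable())
  expect_false(fv3$has_eqtl)
  # unknown target gene errors with the gene named
  expect_error(interactionFeatureVectors(
    tr, data.frame(snp_pos = 52000L, gene_id = "GX"), ann,
    emptyPairTable()), "GX")
  # closest gene to the PIR [50000, 55000): G3 promoter [40000, 41000) at
  # 9 kb beats G4 at 5 kb? no: G4 promoter [60000, 61000) is 5 kb away
  expect_false(fv$closest_gene_in_bait)  # nearest gene G4 is unbaited
  # strong LD flag honors any population
  pr <- data.table::data.table(
    pos_i = c(5000L, 5000L), pos_j = c(52000L, 52000L),
    r2 = c(0.5, 0.9), dprime = c(1, 1), distance = c(47000L, 47000L),
    population = c("EUR", "AFR"))
  fv4 <- interactionFeatureVectors(
    tr, data.frame(snp_pos = 52000L, gene_id = "G1"), ann, pr)
  expect_true(fv4$strong_ld)
})

test_that("quantile distance bins are near-equal and fail on ties", {
  tr <- randomTrack(61, n = 101L, sepRange = c(20000, 1900000))
  qb <- quantileDistanceBins(tr, nBins = 4L)
  counts <- table(qb$bin)
  expect_lte(max(counts) - min(counts), 2)
  tied <- InteractionTrack("chrS", rep(0, 10), rep(5000, 10),
                           rep(100000, 10), rep(105000, 10),
                           score = rep(6, 10))
  expect_error(quantileDistanceBins(tied, nBins = 3L), "tied|collapse")
  expect_error(quantileDistanceBins(subsetInteractions(tr, 1:2), nBins = 4L),
               "fewer")
})

test_that("stratified OR matches arithmetic, Wald theory and IRLS", {
  y <- rep(c(TRUE, FALSE, TRUE, FALSE), c(10, 10, 10, 10))
  x <- rep(c(TRUE, TRUE, FALSE, FALSE), c(10, 10, 10, 10))
  or <- stratifiedOR(y, x, rep("b", 40))
  expect_equal(or$or_estimate, 1)
  expect_gt(or$p, 0.95)
  # (90, 10, 50, 50): OR = 9, CI from the textbook Wald formula
  y2 <- rep(c(TRUE, FALSE, TRUE, FALSE), c(90, 10, 50, 50))
  x2 <- rep(c(TRUE, TRUE, FALSE, FALSE), c(90, 10, 50, 50))
  or2 <- stratifiedOR(y2, x2, rep("b", 200))
  expect_equal(or2$or_estimate, 9)
  se <- sqrt(1 / 90 + 1 / 10 + 1 / 50 + 1 / 50)
  expect_equal(or2$ci_low, exp(log(9) - qnorm(0.975) * se))
  expect_equal(or2$ci_high, exp(log(9) + qnorm(0.975) * se))
  # equivalence with a single-covariate logistic regression (IRLS)
  expect_equal(or2$log_or, irlsLogOr(as.numeric(y2), x2), tolerance = 1e-8)
  # a stratum with one x class is flagged NA
  or3 <- stratifiedOR(c(TRUE, FALSE), c(TRUE, TRUE), c("a", "a"))
  expect_true(is.na(or3$or_estimate))
  expect_match(or3$note, "single x class")
})

test_that("Fisher exact p equals exhaustive enumeration and is symmetric", {
  expect_equal(fisherExact2x2(10, 10, 10, 10)$p, 1)
  f <- fisherExact2x2(20, 5, 5, 20)
  expect_equal(f$or, 16)
  # enumeration oracle over all tables with these margins
  probs <- vapply(0:25, function(a) {
    b <- 25 - a; c_ <- 25 - a; d <- a - 0
    if (b < 0 || c_ < 0 || d < 0) return(0)
    exp(lchoose(25, a) + lchoose(25, 25 - a) - lchoose(50, 25))
  }, 0)
  pObs <- probs[21]
  expect_equal(f$p, sum(probs[probs <= pObs * (1 + 1e-7)]))
  # agreement with the standard implementation
  expect_equal(f$p, stats::fisher.test(matrix(c(20, 5, 5, 20), 2))$p.value)
  # transposition and row/column swaps leave p unchanged
  expect_equal(fisherExact2x2(5, 20, 20, 5)$p, f$p)
  expect_equal(fisherExact2x2(20, 5, 5, 20)$p,
               fisherExact2x2(5, 20, 20, 5)$p)
  expect_error(fisherExact2x2(0, 0, 3, 4), "margins")
  # sample OR agrees with the stratified 2x2 estimate on nonzero cells
  y <- rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 5, 5, 20))
  x <- rep(c(TRUE, TRUE, FALSE, FALSE), c(20, 5, 5, 20))
  expect_equal(stratifiedOR(y, x, rep("s", 50))$or_estimate, f$or)
})

test_that("BH adjustment reproduces the step-up arithmetic", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
  # q ordering preserves p ordering and q >= p
  set.seed(62)
  p <- runif(50)
  q <- bhAdjust(p)
  expect_true(all(q >= p - 1e-12))
  expect_equal(order(q[order(p)]), seq_len(50))
})

test_that("SNP-to-gene strategies match brute-force scans", {
  ann <- fixtureAnnotation()
  # SNP inside a promoter: closest is that gene at distance 0
  expect_equal(snpToGenes(5500L, "closest", ann)[[1]], "G1")
  # SNP in no block: ld_block strategy returns the empty set
  blocks <- data.table::data.table(chrom = "chrS", start = 19500L,
                                   end = 41000L, n_snps = 3L,
                                   population = "POP1")
  expect_length(snpToGenes(5500L, "ld_block", ann, blocks = blocks)[[1]], 0)
  # SNP in the block: all genes with promoters overlapping the block
  expect_equal(snpToGenes(30000L, "ld_block", ann, blocks = blocks)[[1]],
               c("G2", "G3"))
  # pchic: bait genes of significant interactions whose PIR holds the SNP
  tr <- InteractionTrack("chrS", c(4000, 19000, 39000),
                         c(7000, 22000, 42000),
                         c(50000, 50000, 70000),
                         c(55000, 56000, 75000), score = c(6, 6, 2))
  got <- snpToGenes(52000L, "pchic", ann, interactions = tr)[[1]]
  expect_equal(got, c("G1", "G2"))  # third record is not significant
  expect_error(snpToGenes(100L, "ld_block", ann), "blocks")
  expect_error(snpToGenes(100L, "pchic", ann), "interactions")
})

test_that("GO comparison detects a planted term and degrades gracefully", {
  set.seed(63)
  n <- 120L
  a1 <- seq(0L, by = 20000L, length.out = n)
  tr <- InteractionTrack("chrS", a1, a1 + 5000, a1 + 100000,
                         a1 + 105000,
                         score = ifelse(seq_len(n) <= 60, 6, 1))
  ann <- annotationFromBaits(tr, max(a1) + 200000, seed = 63L)
  bait <- ldhic:::baitGeneOf(tr, ann)
  sig <- isSignificant(tr)
  # phenotype SNPs in the PIRs of 25 significant interactions
  pick <- which(sig)[1:25]
  gwas <- data.frame(phenotype = "trait",
                     pos = a1[pick] + 102000L)
  go <- rbind(
    data.frame(gene_id = unique(bait[pick]), term = "GO:HIT"),
    data.frame(gene_id = sample(ann$gene_id, 40), term = "GO:RAND"))
  res <- goEnrichmentCompare(gwas, ann, go, interactions = tr,
                             strategies = "pchic")
  hit <- res$results[term == "GO:HIT"]
  expect_lt(hit$q, 0.05)
  expect_gt(res$results[term == "GO:RAND", q], 0.05)
  expect_equal(res$counts[fdr == 0.05, n_significant], 1L)
  # a phenotype mapping to no genes yields an NA row with a reason
  gwas2 <- data.frame(phenotype = "empty", pos = 1L)
  res2 <- goEnrichmentCompare(gwas2, ann, go, interactions = tr,
                              strategies = "pchic")
  expect_match(res2$results$note[1], "no mapped genes")
})
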