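test_that("config validation enforces the generator invariants", {
  expect_error(simulationConfig(backgroundSwitchRate = 1.5), "rates")
  expect_error(simulationConfig(depth = 0), "depth")
  expect_error(simulationConfig(alpha = -1), "alpha")
  expect_error(simulationConfig(chromLength = 2560001L), "multiple")
  expect_error(
    simulationConfig(domainIntervals = list(c(0, 100000), c(50000, 200000))),
    "non-overlapping")
  expect_error(
    simulationConfig(loopAnchors = list(list(c(50000, 55000), c(10000, 15000)))),
    "ordered")
})

test_that("deterministic switching gives the founder-mixing LD expectations", {
  # hotspot rate 1, background 0, 2 founders: r2 ~ 0 across the hotspot,
  # r2 = 1 within founder-conserved segments at segregating sites
  cfg <- simulationConfig(nHaplotypes = 4000L, nSnps = 40L,
                          chromLength = 100000L, founderCount = 2L,
                          hotspotPositions = 50000,
                          backgroundSwitchRate = 0, hotspotSwitchRate = 1,
                          binSize = 5000L, seed = 3L)
  hp <- simulateHaplotypes(cfg)
  pos <- snpPositions(hp$panel)
  left <- which(pos <= 50000)
  right <- which(pos > 50000)
  stWithin <- r2Dprime(twoLocusCounts(hp$panel, left[1], left[2]))
  expect_equal(unname(stWithin["r2"]), 1)
  stAcross <- r2Dprime(twoLocusCounts(hp$panel, left[1], right[1]))
  expect_lt(stAcross["r2"], 0.01)
  # no switching at all: every pair in perfect LD
  cfg2 <- simulationConfig(nHaplotypes = 400L, nSnps = 20L,
                           chromLength = 50000L, founderCount = 2L,
                           hotspotPositions = numeric(),
                           backgroundSwitchRate = 0, hotspotSwitchRate = 0,
                           binSize = 5000L, seed = 4L)
  hp2 <- simulateHaplotypes(cfg2)
  tab <- pairwiseLDScan(hp2$panel)
  expect_true(all(tab$r2 == 1))
})

test_that("seeded mosaic r2 matches the counting oracle across a hotspot", {
  cfg <- simulationConfig(nHaplotypes = 2000L, nSnps = 60L,
                          chromLength = 200000L, founderCount = 2L,
                          hotspotPositions = 100000,
                          backgroundSwitchRate = 0.002,
                          hotspotSwitchRate = 1.0, binSize = 5000L,
                          seed = 1L)
  hp <- simulateHaplotypes(cfg)
  pan <- hp$panel
  pos <- snpPositions(pan)
  lf <- which(pos <= 100000); rt <- which(pos > 100000)
  across <- vapply(seq_len(30), function(k) {
    i <- sample(lf, 1); j <- sample(rt, 1)
    oracleR2Dprime(sum(pan@alleles[, i] & pan@alleles[, j]),
                   sum(pan@alleles[, i] & !pan@alleles[, j]),
                   sum(!pan@alleles[, i] & pan@alleles[, j]),
                   sum(!pan@alleles[, i] & !pan@alleles[, j]))["r2"]
  }, 0)
  within <- vapply(seq_len(30), function(k) {
    ij <- sort(sample(lf, 2))
    oracleR2Dprime(sum(pan@alleles[, ij[1]] & pan@alleles[, ij[2]]),
                   sum(pan@alleles[, ij[1]] & !pan@alleles[, ij[2]]),
                   sum(!pan@alleles[, ij[1]] & pan@alleles[, ij[2]]),
                   sum(!pan@alleles[, ij[1]] & !pan@alleles[, ij[2]]))["r2"]
  }, 0)
  expect_lt(mean(across), 0.05)
  expect_gt(mean(within), 0.6)
})

test_that("MAF floor drops SNPs and degenerate configurations error", {
  cfg <- simulationConfig(seed = 2L)
  hp <- simulateHaplotypes(cfg)
  expect_true(all(mafs(hp$panel) >= cfg$mafFloor))
  expect_lte(nSnps(hp$panel), cfg$nSnps)
  cfgBad <- simulationConfig(nHaplotypes = 50L, nSnps = 10L,
                             chromLength = 50000L, binSize = 5000L,
                             mafFloor = 0.9, seed = 1L)
  expect_error(simulateHaplotypes(cfgBad), "degenerate MAF")
})

test_that("generators are byte-reproducible under a fixed seed", {
  cfg <- simulationConfig(seed = 11L)
  h1 <- simulateHaplotypes(cfg)
  h2 <- simulateHaplotypes(cfg)
  expect_identical(h1$panel@alleles, h2$panel@alleles)
  expect_identical(h1$panel@positions, h2$panel@positions)
  c1 <- simulateContactMap(cfg)
  c2 <- simulateContactMap(cfg)
  expect_identical(rawCounts(c1$matrix), rawCounts(c2$matrix))
  t1 <- simulateInteractionCalls(c1$matrix, c1$truth, 20L, 30L, seed = 11L)
  t2 <- simulateInteractionCalls(c2$matrix, c2$truth, 20L, 30L, seed = 11L)
  expect_identical(interactionScores(t1), interactionScores(t2))
  expect_identical(anchorOne(t1), anchorOne(t2))
  # a different seed changes the draw
  h3 <- simulateHaplotypes(simulationConfig(seed = 12L))
  expect_false(identical(h1$panel@alleles, h3$panel@alleles))
})

test_that("noise-free contact rates are flat in O/E and boosts are planted", {
  cfg <- simulationConfig(biasSd = 0, domainBoost = 1, loopBoost = 1,
                          seed = 5L)
  cm <- simulateContactMap(cfg)
  r <- cm$truth$rates
  # the generative expected rate depends on distance only
  byd <- r[, .(u = length(unique(round(lambda, 12)))),
           by = .(d = bin_j - bin_i)]
  expect_true(all(byd$u == 1))
  # planted domain boost appears in the generative rates at fixed distance
  cfg2 <- simulationConfig(biasSd = 0, domainBoost = 2, loopBoost = 1,
                           seed = 5L)
  r2 <- simulateContactMap(cfg2)$truth$rates
  at3 <- r2[bin_j - bin_i == 3]
  expect_equal(mean(at3[sameDomain == TRUE, lambda]) /
                 mean(at3[sameDomain == FALSE, lambda]), 2,
               tolerance = 1e-9)
  # mean O/E inside planted domains ~ boost, outside ~ 1, when domains are
  # sparse enough that they neither dominate coverage nor the per-distance
  # expected (simulation, fixed seed; oracle = the generative rates)
  # a slowly varying decay keeps per-bin coverage nearly uniform, so VC
  # normalization is a near-global rescale and the boost survives intact
  cfg3 <- simulationConfig(
    biasSd = 0, domainBoost = 2, depth = 8e6, alpha = 0.1, seed = 6L,
    domainIntervals = list(c(1000000, 1050000), c(1800000, 1850000)))
  sim <- simulateContactMap(cfg3)
  oe <- observedOverExpected(computeExpected(vcNormalize(sim$matrix)))
  dom <- do.call(rbind, cfg3$domainIntervals)
  binDom <- function(b) {
    mid <- (b + 0.5) * cfg3$binSize
    w <- which(dom[, 1] <= mid & mid < dom[, 2])
    if (length(w)) w else 0L
  }
  oe[, d1 := vapply(bin_i, binDom, 0L)]
  oe[, d2 := vapply(bin_j, binDom, 0L)]
  near <- oe[bin_j - bin_i <= 10 & bin_j > bin_i]
  inDom <- near[d1 > 0 & d1 == d2, mean(oe)]
  outDom <- near[d1 == 0 & d2 == 0, mean(oe)]
  expect_equal(inDom / outDom, 2, tolerance = 0.15)
  expect_equal(outDom, 1, tolerance = 0.1)
})

test_that("a strongly boosted loop pair is the top O/E entry at its distance", {
  la <- list(list(c(500000, 505000), c(700000, 705000)))
  cfg <- simulationConfig(biasSd = 0, domainBoost = 1, loopBoost = 8,
                          loopAnchors = la, depth = 4e6, seed = 9L)
  sim <- simulateContactMap(cfg)
  oe <- observedOverExpected(computeExpected(vcNormalize(sim$matrix)))
  d <- (700000 - 500000) %/% cfg$binSize
  atD <- oe[bin_j - bin_i == d]
  top <- atD[which.max(oe)]
  expect_equal(top$bin_i, 100L)
  expect_equal(top$bin_j, 140L)
})

test_that("interaction calls follow the score-5 significance convention", {
  cfg <- simulationConfig(seed = 3L)
  cm <- simulateContactMap(cfg)
  calls <- simulateInteractionCalls(cm$matrix, cm$truth, nPos = 25L,
                                    nNeg = 40L, seed = 3L)
  expect_equal(sum(isSignificant(calls)), 25L)
  expect_true(all(interactionScores(calls)[isSignificant(calls)] >= 5))
  expect_true(all(interactionScores(calls)[!isSignificant(calls)] < 5))
  # boundary semantics: exactly 5.0 is significant, just below is not
  tr <- InteractionTrack("chrS", c(0, 100000), c(5000, 105000),
                         c(50000, 200000), c(55000, 205000),
                         score = c(5.0, 4.999), kind = "pchic")
  expect_identical(isSignificant(tr), c(TRUE, FALSE))
  # nPos = 0: all records non-significant
  none <- simulateInteractionCalls(cm$matrix, cm$truth, nPos = 0L,
                                   nNeg = 15L, seed = 4L)
  expect_false(any(isSignificant(none)))
  # every planted loop appears among the positives when nPos >= loops
  lb <- cm$truth$loopAnchorBins
  sig <- which(isSignificant(calls))
  a1bin <- (start(anchorOne(calls)) - 1L) %/% cfg$binSize
  a2bin <- (start(anchorTwo(calls)) - 1L) %/% cfg$binSize
  for (k in seq_len(nrow(lb)))
    expect_true(any(a1bin[sig] == lb$bin_i[k] & a2bin[sig] == lb$bin_j[k]))
  # capacity check
  expect_error(
    simulateInteractionCalls(cm$matrix, cm$truth, nPos = 10L,
                             nNeg = 200000L, seed = 5L),
    "exceeds")
})

test_that("regulatory fixture plants the requested odds ratios", {
  tr <- randomTrack(21, n = 4000L)
  ann <- annotationFromBaits(tr, 1e7, seed = 21L)
  # OR = 1: eQTL presence independent of significance
  reg <- simulateRegulatoryFixtures(tr, ann, orProximal = 1, orDistal = 1,
                                    baseRate = 0.08, seed = 21L,
                                    chromLength = 1e7)
  emptyPairs <- data.table::data.table(
    pos_i = integer(), pos_j = integer(), r2 = numeric(),
    dprime = numeric(), distance = integer(), population = character())
  fv <- interactionFeatureVectors(tr, reg$eqtls, ann, emptyPairs)
  or0 <- stratifiedOR(fv$has_eqtl, fv$significant,
                      rep("all", nrow(fv)))
  expect_gt(or0$ci_low, 0.6)
  expect_lt(or0$ci_high, 1.5)
  # planted OR 20 proximal / 4 distal recovered within the 95% CI
  reg2 <- simulateRegulatoryFixtures(tr, ann, orProximal = 20, orDistal = 4,
                                     baseRate = 0.05, seed = 22L,
                                     chromLength = 1e7)
  fv2 <- interactionFeatureVectors(tr, reg2$eqtls, ann, emptyPairs)
  bins <- ifelse(fv2$distance < 2e5, "proximal", "distal")
  or2 <- stratifiedOR(fv2$has_eqtl, fv2$significant, bins)
  prox <- or2[or2$stratum == "proximal", ]
  dist <- or2[or2$stratum == "distal", ]
  expect_true(prox$ci_low <= 20 && 20 <= prox$ci_high)
  expect_true(dist$ci_low <= 4 && 4 <= dist$ci_high)
  # impossible probability errors out
  expect_error(
    simulateRegulatoryFixtures(tr, ann, orProximal = 30, orDistal = 4,
                               baseRate = 0.999, seed = 1L,
                               chromLength = 1e7),
    NA)  # formula keeps p < 1 even here
  expect_error(
    simulateRegulatoryFixtures(tr, ann[1:5, ], orProximal = 2,
                               orDistal = 2, baseRate = 0.05, seed = 1L),
    "20 genes")
})

test_that("anchor_ld coupling plants perfect cross-anchor LD", {
  cfg <- simulationConfig(seed = 13L, coupling = "anchor_ld", nLoops = 6L)
  hp <- simulateHaplotypes(cfg)
  pairs <- pairwiseLDScan(hp$panel)
  planted <- hp$truth$plantedLdPairs
  expect_equal(nrow(planted), 6L)
  for (k in seq_len(nrow(planted))) {
    i <- match(planted$pos_i[k], snpPositions(hp$panel))
    j <- match(planted$pos_j[k], snpPositions(hp$panel))
    expect_false(is.na(i) || is.na(j))
    st <- r2Dprime(twoLocusCounts(hp$panel, i, j))
    expect_equal(unname(st["r2"]), 1)
  }
})
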