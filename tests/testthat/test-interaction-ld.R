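test_that("SNP-anchor membership follows the half-open convention", {
  # anchor [1000, 2000) 0-based: 1-based SNP 1001 (0-based 1000) included,
  # 1-based SNP 2001 (0-based 2000) excluded, 2000 (0-based 1999) included
  tr <- InteractionTrack("chrS", 1000, 2000, 5000, 6000, score = 6)
  on <- snpsOnAnchors(c(1001L, 2000L, 2001L, 5001L), tr)
  expect_equal(on$onAnchor1[[1]], c(1001L, 2000L))
  expect_equal(on$onAnchor2[[1]], 5001L)
  # empty side yields an empty vector
  tr2 <- InteractionTrack("chrS", 100, 200, 5000, 6000, score = 6)
  on2 <- snpsOnAnchors(c(5001L), tr2)
  expect_length(on2$onAnchor1[[1]], 0)
  expect_error(snpsOnAnchors(c(10L, 5L), tr), "sorted")
  # random fixture vs brute-force double loop
  set.seed(41)
  trR <- randomTrack(41, n = 30L, chromLength = 5e5,
                     sepRange = c(20000, 100000))
  snps <- sort(sample.int(5e5, 300L))
  onR <- snpsOnAnchors(snps, trR)
  for (k in c(1L, 7L, 30L)) {
    s <- start(anchorOne(trR))[k]; e <- end(anchorOne(trR))[k]
    expect_equal(onR$onAnchor1[[k]], snps[snps >= s & snps <= e])
  }
})

test_that("interaction max LD takes the cross-anchor maximum with 0 fill", {
  tr <- InteractionTrack("chrS", c(0, 20000), c(10000, 30000),
                         c(50000, 80000), c(60000, 90000), score = c(6, 6))
  pairs <- data.table::data.table(
    pos_i = c(5000L, 6000L), pos_j = c(55000L, 56000L),
    r2 = c(1.0, 0.4), dprime = c(1, 1), distance = c(50000L, 50000L),
    population = "POP1")
  ml <- interactionMaxLD(tr, pairs, snps = c(5000L, 6000L, 25000L,
                                             55000L, 56000L, 85000L))
  expect_equal(ml$maxLd, c(1.0, 0))  # second record: no stored pair -> 0
  expect_identical(ml$noSnpPair, c(FALSE, FALSE))
  # an interaction with an empty anchor is flagged
  ml2 <- interactionMaxLD(tr, pairs, snps = c(5000L, 55000L, 56000L))
  expect_true(ml2$noSnpPair[2])
  expect_equal(ml2$maxLd[2], 0)
  # fixture vs brute-force max over the cross product
  set.seed(42)
  trR <- randomTrack(42, n = 25L, chromLength = 4e5,
                     sepRange = c(30000, 150000), anchorWidth = 20000L)
  snps <- sort(sample.int(4e5, 150L))
  pr <- data.table::data.table(
    pos_i = integer(), pos_j = integer(), r2 = numeric(),
    dprime = numeric(), distance = integer(), population = character())
  cnd <- t(combn(sample(snps, 60L), 2))
  pr <- data.table::data.table(pos_i = pmin(cnd[, 1], cnd[, 2]),
                               pos_j = pmax(cnd[, 1], cnd[, 2]),
                               r2 = runif(nrow(cnd)), dprime = 1,
                               distance = abs(cnd[, 1] - cnd[, 2]),
                               population = "POP1")
  got <- interactionMaxLD(trR, pr, snps = snps)
  for (k in seq_len(25L)) {
    s1 <- snps[snps >= start(anchorOne(trR))[k] &
                 snps <= end(anchorOne(trR))[k]]
    s2 <- snps[snps >= start(anchorTwo(trR))[k] &
                 snps <= end(anchorTwo(trR))[k]]
    best <- 0
    for (a in s1) for (b in s2) {
      hit <- pr[pos_i == min(a, b) & pos_j == max(a, b)]
      if (nrow(hit)) best <- max(best, hit$r2)
    }
    expect_equal(got$maxLd[k], best)
  }
})

test_that("log ratio is near 0 for identical sets and antisymmetric", {
  set.seed(43)
  trA <- randomTrack(43, n = 60L, chromLength = 2e6,
                     sepRange = c(20000, 100000))
  snps <- sort(sample.int(2e6, 800L))
  cnd <- t(combn(sample(snps, 120L), 2))
  pr <- data.table::data.table(pos_i = pmin(cnd[, 1], cnd[, 2]),
                               pos_j = pmax(cnd[, 1], cnd[, 2]),
                               r2 = runif(nrow(cnd), 0.01, 1), dprime = 1,
                               distance = abs(cnd[, 1] - cnd[, 2]),
                               population = "POP1")
  r <- interactionLDLogRatio(trA, trA, pr, nBoot = 200L, seed = 1L)
  expect_equal(r$logRatio, 0)
  expect_true(r$ciLow <= 0 && r$ciHigh >= 0)
  trB <- randomTrack(44, n = 60L, chromLength = 2e6,
                     sepRange = c(20000, 100000))
  fw <- interactionLDLogRatio(trA, trB, pr, nBoot = 200L, seed = 1L)
  bw <- interactionLDLogRatio(trB, trA, pr, nBoot = 200L, seed = 1L)
  expect_equal(fw$logRatio, -bw$logRatio)
})

test_that("same-chromosome shuffle preserves geometry exactly", {
  set.seed(45)
  tr <- randomTrack(45, n = 40L, chromLength = 2e6,
                    sepRange = c(20000, 300000))
  sh <- shuffleSameChrom(tr, 2e6, seed = 9L)
  expect_equal(length(sh), length(tr))
  # per-record distance identical (preserved by the joint shift)
  expect_equal(interactionDistances(sh), interactionDistances(tr))
  expect_equal(width(anchorOne(sh)), width(anchorOne(tr)))
  expect_equal(width(anchorTwo(sh)), width(anchorTwo(tr)))
  # all anchors within chromosome bounds
  expect_true(all(start(anchorOne(sh)) >= 1))
  expect_true(all(end(anchorTwo(sh)) <= 2e6))
  # no overlap with the avoided (original) anchors
  ov <- IRanges::findOverlaps(
    c(anchorOne(sh), anchorTwo(sh)),
    c(anchorOne(tr), anchorTwo(tr)))
  expect_length(ov, 0)
  # KS statistic between distance distributions is 0 by construction
  expect_equal(suppressWarnings(
    stats::ks.test(interactionDistances(sh),
                   interactionDistances(tr))$statistic[[1]]), 0)
  expect_error(shuffleSameChrom(tr, 300000, seed = 1L), "extent")
})

test_that("quantile distance matching balances per-bin counts", {
  set.seed(46)
  pos <- randomTrack(46, n = 40L, chromLength = 2e6,
                     sepRange = c(20000, 500000))
  # candidates that replicate the positives' distances exactly
  s1 <- start(anchorOne(pos)) - 1L
  d <- interactionDistances(pos)
  cand <- InteractionTrack("chrS",
                           a1Start = s1 + 7L, a1End = s1 + 5007L,
                           a2Start = s1 + 7L + d, a2End = s1 + 5007L + d,
                           score = rep(1, length(pos)), kind = "pchic")
  m <- quantileDistanceMatch(pos, cand, nBins = 8L, seed = 2L)
  expect_equal(sort(interactionDistances(m)),
               sort(interactionDistances(pos)))
  # nBins = 1 degenerates to simple random sampling
  m1 <- quantileDistanceMatch(pos, cand, nBins = 1L, seed = 3L)
  expect_equal(length(m1), length(pos))
  # an empty candidate bin raises a range-labelled error
  shortCand <- subsetInteractions(cand, interactionDistances(cand) <
                                    stats::median(d))
  expect_error(quantileDistanceMatch(pos, shortCand, nBins = 8L, seed = 4L),
               "distance bin")
  expect_error(quantileDistanceMatch(pos, pos, nBins = 4L, seed = 1L),
               "non-significant")
})

test_that("same-block fraction matches the overlap oracle", {
  tr <- randomTrack(47, n = 30L, chromLength = 1e6,
                    sepRange = c(20000, 200000))
  giant <- data.table::data.table(chrom = "chrS", start = 1L, end = 1000000L,
                                  n_snps = 2L, population = "POP1")
  expect_equal(sameBlockFraction(tr, giant), 1.0)
  none <- data.table::data.table(chrom = "chrS", start = 1L, end = 10L,
                                 n_snps = 2L, population = "POP1")
  expect_equal(sameBlockFraction(tr, none), 0.0)
  set.seed(48)
  bs <- sort(sample.int(900000L, 50L))
  bl <- data.table::data.table(chrom = "chrS", start = bs,
                               end = bs + sample(5000:150000, 50L, TRUE),
                               n_snps = 2L, population = "POP1")
  got <- sameBlockFraction(tr, bl)
  oracle <- mean(vapply(seq_len(length(tr)), function(k) {
    a1s <- start(anchorOne(tr))[k]; a1e <- end(anchorOne(tr))[k]
    a2s <- start(anchorTwo(tr))[k]; a2e <- end(anchorTwo(tr))[k]
    any(bl$start <= a1e & bl$end >= a1s & bl$start <= a2e & bl$end >= a2s)
  }, TRUE))
  expect_equal(got, oracle)
})
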