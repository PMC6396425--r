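#' Simulation configuration for coupled LD / chromatin scenarios
#'
#' Bundles every parameter of the synthetic-data generators and resolves the
#' coupling scenario. The generators emulate the statistical structure of
#' the real inputs the pipeline was designed for: a phased haplotype panel
#' whose LD is block-patterned by recombination hotspots (founder-mosaic
#' model), a binned contact map with power-law distance decay plus
#' contact-domain and loop boosts, CHiCAGO-like interaction scores with the
#' conventional significance threshold of 5, and eQTL/GWAS/GO fixtures with
#' planted odds ratios. Planted truth is machine-readable so recovery can be
#' tested.
#'
#' Couplings:
#' \describe{
#'   \item{independent}{hotspots are drawn uniformly, independent of domain
#'     and loop placement; LD and chromatin structure share only genomic
#'     distance.}
#'   \item{boundary_coincident}{hotspots are placed exactly at contact-domain
#'     boundaries with deterministic switching, so LD blocks and domains
#'     share edges; the scenario uses low background switching so
#'     within-domain LD is strong.}
#'   \item{anchor_ld}{as independent, but one SNP is forced into each loop
#'     anchor and the anchor-2 copy duplicates the anchor-1 alleles, planting
#'     perfect cross-anchor LD on positive interactions.}
#' }
#'
#' @param nHaplotypes number of haplotypes (two per diploid sample).
#' @param nSnps number of SNPs before MAF filtering.
#' @param chromLength chromosome length in bp; must be a multiple of
#'   \code{binSize}.
#' @param founderCount founder haplotypes in the mosaic model.
#' @param hotspotPositions recombination hotspot coordinates (bp); when NULL
#'   they are resolved from the coupling (drawn uniformly for
#'   \code{independent}/\code{anchor_ld}, set to domain boundaries for
#'   \code{boundary_coincident}).
#' @param nHotspots hotspots to draw when \code{hotspotPositions} is NULL.
#' @param backgroundSwitchRate founder-switch probability per inter-SNP
#'   interval away from hotspots.
#' @param hotspotSwitchRate switch probability for intervals containing a
#'   hotspot.
#' @param binSize contact-map bin width (bp), default 5000 (5-kb
#'   resolution).
#' @param alpha power-law exponent of contact decay; rate is proportional to
#'   (distance in bins + 1)^-alpha.
#' @param domainIntervals list of c(start, end) bp intervals
#'   (0-based half-open), non-overlapping and sorted; NULL gives a regular
#'   alternation of 160-kb domains and 96-kb gaps.
#' @param domainBoost multiplicative contact boost for bin pairs inside one
#'   domain (> 1).
#' @param loopAnchors list of interval pairs
#'   \code{list(c(s1, e1), c(s2, e2))}; NULL draws \code{nLoops} single-bin
#'   anchor pairs with separations drawn from \code{loopSepRange}.
#' @param nLoops loops to draw when \code{loopAnchors} is NULL.
#' @param loopSepRange loop separation range in bins (default 3 to 30,
#'   i.e. 15 kb to 150 kb at 5-kb bins: the short-to-mid range where focal
#'   interactions are callable at this resolution and matrix size).
#' @param loopBoost multiplicative boost for loop-anchor bin pairs.
#' @param biasSd lognormal sigma of per-bin visibility bias.
#' @param depth expected total contact count.
#' @param mafFloor minimum minor-allele frequency retained in the panel.
#' @param coupling scenario, see Details.
#' @param seed integer seed; every generator derives its stream from it.
#' @return A validated list of class \code{"ldhicSimConfig"}.
#' @export
simulationConfig <- function(nHaplotypes = 200L, nSnps = 1200L,
                             chromLength = 2560000L, founderCount = 2L,
                             hotspotPositions = NULL, nHotspots = 9L,
                             backgroundSwitchRate = 0.10,
                             hotspotSwitchRate = 0.9,
                             binSize = 5000L, alpha = 1,
                             domainIntervals = NULL, domainBoost = 3,
                             loopAnchors = NULL, nLoops = 12L,
                             loopSepRange = c(3L, 30L), loopBoost = 5,
                             biasSd = 0.3, depth = 1e6, mafFloor = 0.05,
                             coupling = c("independent",
                                          "boundary_coincident",
                                          "anchor_ld"),
                             seed = 1L) {
  coupling <- match.arg(coupling)
  if (chromLength %% binSize != 0)
    stop("chromLength must be a multiple of binSize")
  coupled <- coupling == "boundary_coincident"
  if (is.null(domainIntervals)) {
    # boundary-coincident runs use shorter domains covering ~25% of the
    # chromosome so the top contact quartile can align with them; the other
    # scenarios use 160-kb domains covering ~62%
    if (chromLength >= 512000L) {
      domWidth <- if (coupled) 64000L else 160000L
      starts <- seq(0L, chromLength - 256000L, by = 256000L)
    } else {
      # short chromosomes get one proportionally scaled domain
      domWidth <- as.integer(chromLength * (if (coupled) 0.25 else 0.625))
      starts <- 0L
    }
    domainIntervals <- lapply(starts, function(s) c(s, s + domWidth))
  }
  dm <- do.call(rbind, domainIntervals)
  if (any(dm[, 1] >= dm[, 2]) || is.unsorted(as.vector(t(dm))))
    stop("domain intervals must be sorted and non-overlapping")
  if (coupled) {
    # hotspot switching applies to every interval not contained in a
    # domain, planting strong LD inside domains and none elsewhere
    if (is.null(hotspotPositions))
      hotspotPositions <- sort(unique(as.vector(dm)))
    if (missing(backgroundSwitchRate)) backgroundSwitchRate <- 0.02
    if (missing(hotspotSwitchRate)) hotspotSwitchRate <- 1.0
    # slower decay and deeper sequencing keep the planted domain signal
    # visible after coverage normalization (VC partially absorbs block
    # structure when domain bins dominate their own coverage)
    if (missing(alpha)) alpha <- 0.7
    if (missing(depth)) depth <- 2e6
  }
  if (is.null(loopAnchors)) {
    loopAnchors <- withSeed(seed + 71L, {
      nb <- chromLength %/% binSize
      hi <- min(loopSepRange[2], nb - 2L)
      lo <- min(loopSepRange[1], hi)
      if (hi < 1L) nLoops <- 0L
      sep <- if (nLoops > 0L) sample(lo:hi, nLoops, replace = TRUE)
             else integer()
      b1 <- vapply(sep, function(s) sample.int(nb - s, 1L) - 1L, 0L)
      lapply(seq_len(nLoops), function(k) {
        list(c(b1[k] * binSize, (b1[k] + 1L) * binSize),
             c((b1[k] + sep[k]) * binSize, (b1[k] + sep[k] + 1L) * binSize))
      })
    })
  }
  for (la in loopAnchors)
    if (la[[1]][1] >= la[[2]][1])
      stop("loop anchors must be ordered start1 < start2")
  if (is.null(hotspotPositions)) {
    hotspotPositions <- withSeed(seed + 37L,
      sort(sample.int(chromLength - 20000L, nHotspots) + 10000L))
  }
  cfg <- list(nHaplotypes = as.integer(nHaplotypes),
              nSnps = as.integer(nSnps),
              chromLength = as.integer(chromLength),
              founderCount = as.integer(founderCount),
              hotspotPositions = as.numeric(hotspotPositions),
              backgroundSwitchRate = backgroundSwitchRate,
              hotspotSwitchRate = hotspotSwitchRate,
              binSize = as.integer(binSize), alpha = alpha,
              domainIntervals = domainIntervals, domainBoost = domainBoost,
              loopAnchors = loopAnchors, loopBoost = loopBoost,
              biasSd = biasSd, depth = depth, mafFloor = mafFloor,
              coupling = coupling, seed = as.integer(seed))
  rates <- c(cfg$backgroundSwitchRate, cfg$hotspotSwitchRate, cfg$mafFloor)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$depth <= 0) stop("depth must be positive")
  if (cfg$alpha <= 0) stop("alpha must be positive")
  if (any(cfg$hotspotPositions < 0 | cfg$hotspotPositions >= chromLength))
    stop("hotspot positions must lie within [0, chromLength)")
  class(cfg) <- "ldhicSimConfig"
  cfg
}

#' Simulate a phased haplotype panel with planted LD-block structure
#'
#' Founder-mosaic model: \code{founderCount} founder haplotypes are drawn
#' i.i.d. Bernoulli(0.5) per site; each haplotype starts on a uniformly
#' chosen founder and, between consecutive SNPs, re-draws its founder
#' uniformly with the interval's switch probability
#' (\code{hotspotSwitchRate} when a hotspot lies in the interval,
#' \code{backgroundSwitchRate} otherwise). Hotspots therefore break LD
#' locally while founder-conserved segments carry perfect association,
#' giving direct control over planted block boundaries at O(haplotypes x
#' SNPs) cost. SNPs below the MAF floor are dropped. Under the
#' \code{anchor_ld} coupling one SNP is forced into each loop anchor and the
#' anchor-2 SNP copies the anchor-1 alleles.
#'
#' @param config a [simulationConfig()].
#' @return List with \code{panel} (a [HaplotypePanel-class]) and
#'   \code{truth} (hotspot positions, planted cross-anchor SNP pairs, seed).
#' @export
simulateHaplotypes <- function(config) {
  stopifnot(inherits(config, "ldhicSimConfig"))
  if (config$nSnps < 2L) stop("need at least 2 SNPs")
  if (config$founderCount < 2L) stop("need at least 2 founders")
  withSeed(config$seed + 11L, {
    forced <- integer()
    if (config$coupling == "anchor_ld") {
      forced <- unlist(lapply(config$loopAnchors, function(la)
        c(floor((la[[1]][1] + la[[1]][2]) / 2),
          floor((la[[2]][1] + la[[2]][2]) / 2))))
      forced <- as.integer(forced) + 1L  # 1-based SNP positions
    }
    free <- sample.int(config$chromLength, config$nSnps)
    pos <- sort(unique(c(forced, free)))
    if (length(pos) > config$nSnps && length(forced) == 0L)
      pos <- sort(sample(pos, config$nSnps))
    n <- length(pos)
    if (any(diff(pos) <= 0)) stop("non-increasing SNP positions")
    F <- matrix(rbinom(config$founderCount * n, 1L, 0.5),
                config$founderCount, n)
    hs <- sort(config$hotspotPositions)
    if (config$coupling == "boundary_coincident") {
      # low switching only for intervals wholly inside a domain; gaps and
      # boundary-crossing intervals switch at the hotspot rate
      dm <- do.call(rbind, config$domainIntervals)
      rate <- vapply(seq_len(n - 1L), function(k) {
        inside <- any(dm[, 1] <= pos[k] & pos[k + 1L] <= dm[, 2])
        if (inside) config$backgroundSwitchRate else config$hotspotSwitchRate
      }, 0)
    } else {
      # interval k spans (pos[k], pos[k+1]]; hotspots are 0-based bp
      rate <- ifelse(vapply(seq_len(n - 1L), function(k)
        any(hs > pos[k] & hs <= pos[k + 1L]), TRUE),
        config$hotspotSwitchRate, config$backgroundSwitchRate)
    }
    nh <- config$nHaplotypes
    path <- matrix(0L, nh, n)
    path[, 1] <- sample.int(config$founderCount, nh, replace = TRUE)
    swAll <- matrix(runif(nh * (n - 1L)), nh, n - 1L) <
      matrix(rate, nh, n - 1L, byrow = TRUE)
    redraw <- matrix(sample.int(config$founderCount, nh * (n - 1L),
                                replace = TRUE), nh, n - 1L)
    for (k in 2:n) {
      prev <- path[, k - 1L]
      sw <- swAll[, k - 1L]
      prev[sw] <- redraw[sw, k - 1L]
      path[, k] <- prev
    }
    alleles <- matrix(F[cbind(as.vector(path),
                              rep(seq_len(n), each = nh))], nh, n)
    plantedPairs <- NULL
    if (config$coupling == "anchor_ld") {
      idx <- match(forced, pos)
      for (m in seq_len(length(idx) / 2L)) {
        i1 <- idx[2L * m - 1L]; i2 <- idx[2L * m]
        alleles[, i2] <- alleles[, i1]
        # guarantee the planted pair survives the MAF floor
        if (min(mean(alleles[, i1]), 1 - mean(alleles[, i1])) <
            config$mafFloor) {
          alleles[, i1] <- rep_len(c(0L, 1L), nh)
          alleles[, i2] <- alleles[, i1]
        }
      }
      plantedPairs <- data.table(pos_i = pmin(forced[c(TRUE, FALSE)],
                                              forced[c(FALSE, TRUE)]),
                                 pos_j = pmax(forced[c(TRUE, FALSE)],
                                              forced[c(FALSE, TRUE)]))
    }
    f <- colMeans(alleles)
    keep <- pmin(f, 1 - f) >= config$mafFloor
    if (config$coupling == "anchor_ld") keep[match(forced, pos)] <- TRUE
    if (sum(keep) < 2L)
      stop("degenerate MAF configuration: fewer than 2 SNPs pass the floor")
    panel <- HaplotypePanel(alleles[, keep, drop = FALSE], pos[keep],
                            chrom = "chrS", samplePopulation = "POP1")
    list(panel = panel,
         truth = list(hotspotPositions = config$hotspotPositions,
                      plantedLdPairs = plantedPairs, seed = config$seed))
  })
}

#' Simulate a binned contact map with domains and loops
#'
#' Counts are Poisson with rate proportional to
#' \eqn{b_i b_j (|i-j|+1)^{-\alpha}}, multiplied by \code{domainBoost} when
#' both bin midpoints fall in the same planted domain and by
#' \code{loopBoost} for planted loop-anchor bin pairs; \eqn{b} are lognormal
#' per-bin visibility biases. Rates are rescaled so the expected total count
#' equals \code{depth}. Only the upper triangle (i <= j) is stored.
#'
#' @param config a [simulationConfig()].
#' @return List with \code{matrix} (a [ContactMatrix-class]) and
#'   \code{truth} (domain boundaries, loop-anchor bin pairs, generative
#'   rates as a data.table).
#' @export
simulateContactMap <- function(config) {
  stopifnot(inherits(config, "ldhicSimConfig"))
  nb <- config$chromLength %/% config$binSize
  if (nb < 10L) stop("need at least 10 bins")
  withSeed(config$seed + 23L, {
    b <- if (config$biasSd > 0) rlnorm(nb, 0, config$biasSd) else rep(1, nb)
    # upper triangle incl. diagonal, column by column
    j <- rep.int(seq_len(nb), seq_len(nb))
    i <- sequence(seq_len(nb))
    mid <- (seq_len(nb) - 0.5) * config$binSize
    dm <- do.call(rbind, config$domainIntervals)
    binDom <- rep(0L, nb)
    for (d in seq_len(nrow(dm)))
      binDom[mid >= dm[d, 1] & mid < dm[d, 2]] <- d
    sameDom <- binDom[i] > 0L & binDom[i] == binDom[j]
    rate <- b[i] * b[j] * (abs(j - i) + 1)^(-config$alpha)
    rate[sameDom] <- rate[sameDom] * config$domainBoost
    loopBins <- vapply(config$loopAnchors, function(la)
      c(floor((la[[1]][1] + la[[1]][2]) / 2) %/% config$binSize,
        floor((la[[2]][1] + la[[2]][2]) / 2) %/% config$binSize),
      c(0, 0))
    if (length(loopBins)) {
      key <- (pmin(loopBins[1, ], loopBins[2, ]) + 1) * (nb + 1) +
             pmax(loopBins[1, ], loopBins[2, ]) + 1
      isLoop <- (i * (nb + 1) + j) %in% key
      rate[isLoop] <- rate[isLoop] * config$loopBoost
    }
    if (any(!is.finite(rate))) stop("non-finite expected contact rate")
    lambda <- rate * config$depth / sum(rate)
    cnt <- rpois(length(lambda), lambda)
    keep <- cnt > 0
    cm <- ContactMatrix(i[keep] - 1L, j[keep] - 1L, cnt[keep], nBins = nb,
                        binSize = config$binSize, chrom = "chrS")
    truth <- list(domainBoundaries = sort(unique(as.vector(dm))),
                  loopAnchorBins = if (length(loopBins))
                    data.table(bin_i = pmin(loopBins[1, ], loopBins[2, ]),
                               bin_j = pmax(loopBins[1, ], loopBins[2, ]))
                  else data.table(bin_i = integer(), bin_j = integer()),
                  rates = data.table(bin_i = i - 1L, bin_j = j - 1L,
                                     lambda = lambda, sameDomain = sameDom),
                  seed = config$seed)
    list(matrix = cm, truth = truth)
  })
}

#' Simulate interaction calls from a contact map
#'
#' Positives are anchored at planted loops plus the highest observed /
#' expected bin pairs and receive shifted-exponential scores >= 5; negatives
#' are random other bin pairs with scores below 5. Records follow the
#' promoter-capture convention: score >= 5 is significant, anchors are
#' 0-based half-open bin intervals and distance is midpoint-to-midpoint.
#'
#' @param matrix a [ContactMatrix-class].
#' @param truth truth list from [simulateContactMap()] (for planted loops).
#' @param nPos,nNeg numbers of significant / non-significant records.
#' @param seed integer seed.
#' @param minBinSep minimum bin separation for sampled pairs.
#' @param anchorBins anchor width in bins (default 2, i.e. 10-kb fragments
#'   at 5-kb resolution, comparable to capture fragment sizes).
#' @return An [InteractionTrack-class] (kind "pchic").
#' @export
simulateInteractionCalls <- function(matrix, truth, nPos, nNeg, seed,
                                     minBinSep = 3L, anchorBins = 2L,
                                     maxBinSep = 30L) {
  nb <- nBins(matrix)
  withSeed(seed + 31L, {
    m <- if (isNormalized(matrix)) matrix else vcNormalize(matrix)
    if (!length(m@expected)) m <- computeExpected(m)
    oe <- observedOverExpected(m)
    loops <- truth$loopAnchorBins
    posPairs <- as.data.table(loops)[, .(bin_i, bin_j)]
    if (nrow(posPairs) < nPos) {
      cand <- oe[bin_j - bin_i >= minBinSep & bin_j - bin_i <= maxBinSep]
      cand <- cand[!paste(bin_i, bin_j) %in%
                     paste(posPairs$bin_i, posPairs$bin_j)]
      cand <- cand[order(-oe)]
      need <- nPos - nrow(posPairs)
      # keep records statistically distinct: no bin anchors two positives
      usedBins <- unique(c(posPairs$bin_i, posPairs$bin_j))
      keepIdx <- integer()
      for (r in seq_len(nrow(cand))) {
        if (length(keepIdx) >= need) break
        bi <- cand$bin_i[r]; bj <- cand$bin_j[r]
        if (bi %in% usedBins || bj %in% usedBins) next
        keepIdx <- c(keepIdx, r)
        usedBins <- c(usedBins, bi, bj)
      }
      if (length(keepIdx) < need)
        stop("not enough candidate bin pairs for the requested positives")
      posPairs <- rbind(posPairs, cand[keepIdx, .(bin_i, bin_j)])
    } else {
      posPairs <- posPairs[seq_len(max(nPos, 0L)), ]
    }
    nPairsAvail <- nb * (nb - 1L) / 2
    if (nPos + nNeg > nPairsAvail)
      stop("nPos + nNeg exceeds the number of available bin pairs")
    negI <- integer(nNeg); negJ <- integer(nNeg)
    usedKey <- paste(posPairs$bin_i, posPairs$bin_j)
    k <- 0L
    while (k < nNeg) {
      bi <- sample.int(nb, 1L) - 1L
      sep <- sample(minBinSep:min(maxBinSep, nb - 1L), 1L)
      bj <- bi + sep
      if (bj >= nb) next
      key <- paste(bi, bj)
      if (key %in% usedKey) next
      k <- k + 1L
      negI[k] <- bi; negJ[k] <- bj
      usedKey <- c(usedKey, key)
    }
    bi <- c(posPairs$bin_i, negI)
    bj <- c(posPairs$bin_j, negJ)
    score <- c(5 + rexp(nrow(posPairs), rate = 1),
               runif(nNeg, 0, 5 - 1e-9))
    bs <- binSize(matrix)
    aw <- as.integer(anchorBins)
    # shift (never truncate) anchors at the chromosome end so every anchor
    # keeps the same width and all distances stay on the bin grid
    b1s <- pmin(bi, nb - aw)
    b2s <- pmin(bj, nb - aw)
    InteractionTrack(chrom = m@chrom,
                     a1Start = b1s * bs, a1End = (b1s + aw) * bs,
                     a2Start = b2s * bs, a2End = (b2s + aw) * bs,
                     score = score, kind = "pchic")
  })
}

#' Gene annotation aligned to interaction baits
#'
#' Builds a minimal gene annotation for synthetic runs: one gene per
#' distinct bait (anchor-1) fragment with its TSS at the bait midpoint and a
#' 2-kb promoter around it, plus unbaited filler genes at uniform positions.
#' Coordinates are 0-based half-open, matching the annotation reader.
#'
#' @param interactions an [InteractionTrack-class].
#' @param chromLength chromosome length (bp).
#' @param nFiller unbaited genes to add.
#' @param seed integer seed.
#' @return A gene annotation data.table (see [geneAnnotation()]).
#' @export
annotationFromBaits <- function(interactions, chromLength, nFiller = 20L,
                                seed = 1L) {
  withSeed(seed + 43L, {
    baitS <- start(anchorOne(interactions)) - 1L  # back to 0-based
    baitE <- end(anchorOne(interactions))
    key <- !duplicated(paste(baitS, baitE))
    baitS <- baitS[key]; baitE <- baitE[key]
    tss <- as.integer(floor((baitS + baitE) / 2))
    fillerTss <- sort(sample.int(chromLength - 2000L, nFiller) + 1000L)
    geneAnnotation(
      gene_id = sprintf("G%04d", seq_len(length(tss) + nFiller)),
      tss = c(tss, fillerTss),
      promoter_start = c(pmax(tss - 1000L, 0L), fillerTss - 1000L),
      promoter_end = c(tss + 1000L, fillerTss + 1000L),
      bait_start = c(baitS, rep(NA_integer_, nFiller)),
      bait_end = c(baitE, rep(NA_integer_, nFiller)),
      chrom = interactions@chrom)
  })
}

#' Simulate eQTL, GWAS and GO fixtures with planted enrichment
#'
#' Each interaction emits an eQTL (SNP uniform in the PIR, target gene the
#' bait gene) with probability
#' \eqn{b\,\mathrm{OR} / (1 - b + b\,\mathrm{OR})} when significant and
#' \eqn{b} otherwise, where OR is \code{orProximal} below 200 kb and
#' \code{orDistal} beyond, so the marginal significant-vs-eQTL odds ratio
#' equals the planted OR in each distance stratum. GWAS SNPs for the
#' planted phenotype are placed in the PIRs of a sample of significant
#' interactions, and one planted GO term is attached to the bait genes of
#' those interactions; background terms are assigned at random. A second,
#' background phenotype receives SNPs at uniform positions.
#'
#' @param interactions an [InteractionTrack-class].
#' @param annotation a gene annotation (see [geneAnnotation()]).
#' @param orProximal,orDistal planted odds ratios (>= 1).
#' @param baseRate eQTL base rate for non-significant interactions.
#' @param seed integer seed.
#' @param chromLength chromosome length (bp) for background SNP placement.
#' @param nGwasPerPhenotype GWAS SNPs per phenotype.
#' @param nBackgroundTerms background GO terms.
#' @return List with \code{eqtls} (snp_pos, gene_id), \code{gwas}
#'   (phenotype, pos), \code{go} (gene_id -> term list as a long
#'   data.table), and \code{truth}.
#' @export
simulateRegulatoryFixtures <- function(interactions, annotation, orProximal,
                                       orDistal, baseRate, seed,
                                       chromLength = NULL,
                                       nGwasPerPhenotype = 25L,
                                       nBackgroundTerms = 20L) {
  if (nrow(annotation) < 20L) stop("annotation must contain >= 20 genes")
  if (orProximal < 1 || orDistal < 1) stop("planted ORs must be >= 1")
  withSeed(seed + 53L, {
    n <- length(interactions)
    dist <- interactionDistances(interactions)
    sig <- isSignificant(interactions)
    OR <- ifelse(dist < 2e5, orProximal, orDistal)
    pSig <- baseRate * OR / (1 - baseRate + baseRate * OR)
    if (any(pSig >= 1)) stop("baseRate and OR imply eQTL probability >= 1")
    p <- ifelse(sig, pSig, baseRate)
    hasEqtl <- runif(n) < p
    baitGene <- baitGeneOf(interactions, annotation)
    hasEqtl[is.na(baitGene)] <- FALSE
    pirS <- start(anchorTwo(interactions)) - 1L
    pirW <- width(anchorTwo(interactions))
    snpPos <- pirS + floor(runif(n) * pirW) + 1L  # 1-based inside PIR
    eqtls <- data.table(snp_pos = snpPos[hasEqtl],
                        gene_id = baitGene[hasEqtl])
    # GWAS: planted phenotype tags PIRs of significant interactions
    sigIdx <- which(sig & !is.na(baitGene))
    pick <- sigIdx[seq_len(min(nGwasPerPhenotype, length(sigIdx)))]
    gwasPlanted <- data.table(phenotype = "planted_trait",
                              pos = snpPos[pick])
    if (is.null(chromLength))
      chromLength <- max(end(anchorTwo(interactions)))
    gwasBg <- data.table(phenotype = "background_trait",
                         pos = sample.int(chromLength, nGwasPerPhenotype))
    gwas <- rbind(gwasPlanted, gwasBg)
    # GO: planted term on bait genes of SNP-bearing interactions
    plantedGenes <- unique(baitGene[pick])
    genes <- annotation$gene_id
    goPlanted <- data.table(gene_id = plantedGenes, term = "GO:PLANTED")
    bgTerms <- sprintf("GO:BG%03d", seq_len(nBackgroundTerms))
    goBg <- data.table::rbindlist(lapply(bgTerms, function(tm) {
      memb <- genes[runif(length(genes)) < 0.15]
      if (!length(memb)) memb <- sample(genes, 1L)
      data.table(gene_id = memb, term = tm)
    }))
    go <- rbind(goPlanted, goBg)
    truth <- list(orProximal = orProximal, orDistal = orDistal,
                  enrichedTerms = data.table(phenotype = "planted_trait",
                                             term = "GO:PLANTED"),
                  eqtlPairs = eqtls, seed = seed)
    list(eqtls = eqtls, gwas = gwas, go = go, truth = truth)
  })
}

#' Fraction of planted hotspots recovered by called block edges
#'
#' A hotspot is recovered when a block start or end lies within one
#' inter-SNP gap of it: with flanking SNPs \code{pos[k] <= h < pos[k+1]},
#' an edge in \code{[pos[k-1], pos[k+2]]} counts.
#'
#' @param blocks block table from [callLDBlocks()].
#' @param hotspots hotspot positions (bp).
#' @param positions SNP positions of the scanned panel.
#' @return Fraction of hotspots recovered.
#' @export
hotspotRecovery <- function(blocks, hotspots, positions) {
  if (!length(hotspots)) return(NA_real_)
  edges <- c(blocks$start, blocks$end)
  pos <- sort(positions)
  n <- length(pos)
  hit <- vapply(hotspots, function(h) {
    k <- findInterval(h, pos)
    lo <- pos[max(k - 1L, 1L)]
    hi <- pos[min(k + 2L, n)]
    if (k == 0L) { lo <- pos[1]; hi <- pos[min(2L, n)] }
    any(edges >= lo & edges <= hi)
  }, TRUE)
  mean(hit)
}

# bait gene of each interaction: the annotated gene whose bait fragment
# equals the record's anchor-1 fragment (NA when none)
baitGeneOf <- function(interactions, annotation) {
  s <- start(anchorOne(interactions)) - 1L
  e <- end(anchorOne(interactions))
  key <- paste(s, e)
  ann <- annotation[!is.na(annotation$bait_start), ]
  annKey <- paste(ann$bait_start, ann$bait_end)
  ann$gene_id[match(key, annKey)]
}
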