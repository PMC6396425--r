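#' SNPs falling on each interaction anchor
#'
#' Half-open interval membership of 1-based SNP positions in the 0-based
#' half-open anchor fragments (a SNP at the anchor start is included, one
#' at the anchor end is excluded). Both anchors are considered.
#'
#' @param snps sorted 1-based SNP positions.
#' @param interactions an [InteractionTrack-class].
#' @return List with elements \code{onAnchor1} and \code{onAnchor2}, each a
#'   list (per interaction) of SNP positions.
#' @export
snpsOnAnchors <- function(snps, interactions) {
  if (is.unsorted(snps)) stop("SNP positions must be sorted")
  sr <- IRanges(start = snps, end = snps)
  per <- function(anch) {
    ov <- findOverlaps(sr, anch)
    out <- vector("list", length(anch))
    sp <- split(snps[queryHits(ov)], subjectHits(ov))
    out[as.integer(names(sp))] <- sp
    out[vapply(out, is.null, TRUE)] <- list(integer())
    out
  }
  list(onAnchor1 = per(anchorOne(interactions)),
       onAnchor2 = per(anchorTwo(interactions)))
}

#' Maximum cross-anchor LD per interaction
#'
#' For each interaction, the maximum stored r-squared over SNP pairs with
#' one member on each anchor. Pairs absent from the table (below the
#' storage floor) contribute 0; interactions with no SNP on one or both
#' anchors yield 0 with the \code{noSnpPair} flag set.
#'
#' @param interactions an [InteractionTrack-class].
#' @param pairs LD pair table from [pairwiseLDScan()] (one population, or
#'   filter before calling).
#' @param snps SNP positions to intersect with anchors; defaults to all
#'   positions appearing in \code{pairs}.
#' @return data.table: maxLd, noSnpPair (TRUE when an anchor had no SNP).
#' @export
interactionMaxLD <- function(interactions, pairs, snps = NULL) {
  pr <- as.data.table(pairs)
  if (length(unique(pr$population)) > 1)
    stop("supply a single population's pair table")
  if (is.null(snps)) snps <- sort(unique(c(pr$pos_i, pr$pos_j)))
  on <- snpsOnAnchors(snps, interactions)
  n <- length(interactions)
  n1 <- lengths(on$onAnchor1)
  n2 <- lengths(on$onAnchor2)
  noPair <- n1 == 0L | n2 == 0L
  maxLd <- numeric(n)
  ok <- which(!noPair)
  if (length(ok)) {
    # one keyed join over the concatenated cross products of all records
    cross <- data.table(
      rec = rep(ok, times = (n1 * n2)[ok]),
      p1 = unlist(lapply(ok, function(k)
        rep(on$onAnchor1[[k]], each = n2[k]))),
      p2 = unlist(lapply(ok, function(k)
        rep(on$onAnchor2[[k]], times = n1[k]))))
    cross[, `:=`(pos_i = pmin(p1, p2), pos_j = pmax(p1, p2))]
    setkey(pr, pos_i, pos_j)
    cross[, r2 := pr[cross, on = c("pos_i", "pos_j"), x.r2]]
    got <- cross[!is.na(r2), .(m = max(r2)), by = rec]
    maxLd[got$rec] <- got$m
  }
  data.table(maxLd = maxLd, noSnpPair = noPair)
}

#' Log ratio of mean interaction LD, significant vs matched
#'
#' The per-interaction maximum cross-anchor r-squared is averaged
#' separately over significant (positive) and distance-matched
#' non-significant (negative) interactions; the statistic is the natural
#' log of the ratio of means, with a nonparametric bootstrap CI over
#' interactions. A value near 0 indicates LD carries no information about
#' interaction significance. Interactions with no SNP pair contribute 0 by
#' default; set \code{dropEmpty = TRUE} to exclude them from the means.
#'
#' @param positives,negatives [InteractionTrack-class] objects.
#' @param pairs LD pair table (one population).
#' @param nBoot bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @param dropEmpty drop interactions with no SNP on an anchor.
#' @param conf CI level.
#' @param ciMethod "bca" (default; bias-corrected and accelerated, with
#'   jackknife acceleration over interactions) or "percentile".
#' @return List: meanPos, meanNeg, logRatio, ciLow, ciHigh, nPos, nNeg.
#' @export
interactionLDLogRatio <- function(positives, negatives, pairs,
                                  nBoot = 1000L, seed = 1L,
                                  dropEmpty = FALSE, conf = 0.95,
                                  ciMethod = c("bca", "percentile")) {
  ciMethod <- match.arg(ciMethod)
  lp <- interactionMaxLD(positives, pairs)
  ln <- interactionMaxLD(negatives, pairs)
  vp <- if (dropEmpty) lp$maxLd[!lp$noSnpPair] else lp$maxLd
  vn <- if (dropEmpty) ln$maxLd[!ln$noSnpPair] else ln$maxLd
  if (!length(vp) || !length(vn)) stop("empty interaction set")
  mp <- mean(vp); mn <- mean(vn)
  if (mn == 0)
    stop("mean negative LD is zero (no SNP pairs on negatives); ",
         "log ratio undefined")
  lr <- log(mp / mn)
  boots <- withSeed(seed + 97L, vapply(seq_len(nBoot), function(b) {
    bp <- mean(vp[sample.int(length(vp), replace = TRUE)])
    bn <- mean(vn[sample.int(length(vn), replace = TRUE)])
    if (bp == 0 || bn == 0) NA_real_ else log(bp / bn)
  }, 0))
  boots <- boots[is.finite(boots)]
  alpha <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  if (ciMethod == "percentile" || length(boots) < 10L) {
    qs <- quantile(boots, alpha, names = FALSE)
  } else {
    # BCa: bias correction from the bootstrap distribution, acceleration
    # from a two-sample jackknife over interactions
    z0 <- qnorm(mean(boots < lr))
    jp <- if (length(vp) > 1)
      vapply(seq_along(vp), function(i)
        log(mean(vp[-i]) / mn), 0) else lr
    jn <- if (length(vn) > 1)
      vapply(seq_along(vn), function(i)
        log(mp / mean(vn[-i])), 0) else lr
    jack <- c(jp, jn)
    jack <- jack[is.finite(jack)]
    u <- mean(jack) - jack
    denom <- 6 * sum(u^2)^1.5
    acc <- if (denom > 0) sum(u^3) / denom else 0
    zA <- qnorm(alpha)
    adj <- pnorm(z0 + (z0 + zA) / (1 - acc * (z0 + zA)))
    qs <- quantile(boots, pmin(pmax(adj, 0), 1), names = FALSE)
  }
  list(meanPos = mp, meanNeg = mn, logRatio = lr,
       ciLow = qs[1], ciHigh = qs[2], nPos = length(vp), nNeg = length(vn))
}

#' Distance-preserving shuffle along the chromosome
#'
#' Each interaction is jointly shifted to a uniform random position on the
#' same chromosome, preserving both anchor lengths and their separation, so
#' the shuffled set is exactly distance-matched to the input. Shifted
#' records overlapping any anchor of \code{avoid} (default: the input's own
#' anchors) are redrawn, up to \code{maxAttempts} per record. Shuffled
#' records are marked non-significant with score 0.
#'
#' @param interactions an [InteractionTrack-class].
#' @param chromLength chromosome length (bp).
#' @param seed integer seed.
#' @param avoid track whose anchors must not be overlapped (NULL disables).
#' @param maxAttempts redraw cap per record.
#' @return An [InteractionTrack-class] of matched negatives.
#' @export
shuffleSameChrom <- function(interactions, chromLength, seed,
                             avoid = interactions, maxAttempts = 200L) {
  n <- length(interactions)
  s1 <- start(anchorOne(interactions)) - 1L
  e1 <- end(anchorOne(interactions))
  s2 <- start(anchorTwo(interactions)) - 1L
  e2 <- end(anchorTwo(interactions))
  extent <- e2 - s1
  if (any(extent >= chromLength))
    stop("chromLength must exceed the largest interaction extent")
  # merged avoid intervals (0-based half-open) for a findInterval test
  avS <- avE <- numeric(0)
  if (!is.null(avoid)) {
    ar <- IRanges::reduce(c(anchorOne(avoid), anchorTwo(avoid)))
    avS <- start(ar) - 1L
    avE <- end(ar)
  }
  # an interval [s, e) overlaps some avoid interval unless it fits in a gap
  clear <- function(s, e) {
    if (!length(avS)) return(rep(TRUE, length(s)))
    i <- findInterval(s, avS)               # last avoid start <= s
    leftClear <- i == 0L | avE[pmax(i, 1L)] <= s
    j <- findInterval(e - 1e-9, avS)        # last avoid start < e
    leftClear & j == i                      # no avoid interval starts in [s, e)
  }
  withSeed(seed + 59L, {
    ns1 <- integer(n)
    batch <- 32L
    for (k in seq_len(n)) {
      ok <- FALSE
      for (a in seq_len(ceiling(maxAttempts / batch))) {
        u <- sample.int(chromLength - extent[k] + 1L, batch,
                        replace = TRUE) - 1L
        sh <- u - s1[k]
        good <- clear(s1[k] + sh, e1[k] + sh) & clear(s2[k] + sh, e2[k] + sh)
        if (any(good)) {
          ns1[k] <- u[which(good)[1]]; ok <- TRUE; break
        }
      }
      if (!ok)
        stop("could not place shuffled record ", k, " after ",
             maxAttempts, " attempts")
    }
    sh <- ns1 - s1
    InteractionTrack(chrom = interactions@chrom,
                     a1Start = s1 + sh, a1End = e1 + sh,
                     a2Start = s2 + sh, a2End = e2 + sh,
                     score = rep(0, n), kind = interactions@kind,
                     significant = rep(FALSE, n))
  })
}

#' Quantile distance matching of negatives to positives
#'
#' Positives are binned by the empirical quantiles of their distances;
#' candidate non-significant interactions are sampled without replacement
#' from each bin to match the positive count per bin, yielding a
#' distance-matched negative set.
#'
#' @param positives significant interactions.
#' @param candidates non-significant candidate pool.
#' @param nBins number of quantile bins (default 20).
#' @param seed integer seed.
#' @return An [InteractionTrack-class] of matched negatives.
#' @export
quantileDistanceMatch <- function(positives, candidates, nBins = 20L,
                                  seed = 1L) {
  if (any(isSignificant(candidates)))
    stop("candidates must be non-significant")
  dp <- interactionDistances(positives)
  dc <- interactionDistances(candidates)
  edges <- unique(quantile(dp, seq(0, 1, length.out = nBins + 1L),
                           names = FALSE))
  binOf <- function(d) pmax(pmin(findInterval(d, edges, left.open = TRUE),
                                 length(edges) - 1L), 1L)
  bp <- binOf(dp)
  # candidates outside the positive distance range cannot be matched
  inRange <- dc >= edges[1] & dc <= edges[length(edges)]
  bc <- rep(NA_integer_, length(dc))
  bc[inRange] <- binOf(dc[inRange])
  withSeed(seed + 61L, {
    takeIdx <- integer()
    for (b in sort(unique(bp))) {
      need <- sum(bp == b)
      pool <- which(!is.na(bc) & bc == b)
      if (length(pool) < need)
        stop(sprintf(
          "not enough candidates in distance bin [%g, %g]: need %d, have %d",
          edges[b], edges[b + 1L], need, length(pool)))
      takeIdx <- c(takeIdx, pool[sample.int(length(pool), need)])
    }
    subsetInteractions(candidates, sort(takeIdx))
  })
}

#' Fraction of interactions with both anchors in one LD block
#'
#' An interaction counts when at least one block overlaps both of its
#' anchors; the fraction is taken over all interactions. This is the
#' "same-LD-block" rate used to judge how often interacting fragments are
#' genetically linked.
#'
#' @param interactions an [InteractionTrack-class].
#' @param blocks block table from [callLDBlocks()].
#' @return Fraction in \[0, 1\].
#' @export
sameBlockFraction <- function(interactions, blocks) {
  n <- length(interactions)
  if (!n) return(NA_real_)
  if (!nrow(blocks)) return(0)
  br <- IRanges(start = blocks$start, end = blocks$end)
  ov1 <- findOverlaps(anchorOne(interactions), br)
  ov2 <- findOverlaps(anchorTwo(interactions), br)
  k1 <- paste(queryHits(ov1), subjectHits(ov1))
  k2 <- paste(queryHits(ov2), subjectHits(ov2))
  both <- unique(as.integer(sub(" .*", "", intersect(k1, k2))))
  length(both) / n
}
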