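#' Build the bin-pair track joining LD summaries and contact values
#'
#' Aggregates pairwise LD to the contact-map resolution: for each ordered
#' bin pair, the LD summary is the 75th percentile (linear interpolation) of
#' r-squared over SNP pairs whose members fall in the respective bins, and
#' the contact value is the observed/expected entry (0 for included-bin
#' pairs with no stored contact). Sub-floor SNP pairs were dropped from
#' storage upstream; when \code{positions} is supplied they are counted
#' back in as zeros, matching the convention that sub-threshold pairs carry
#' r-squared 0. Bin pairs with neither an LD summary nor a defined contact
#' value are dropped, as are pairs involving excluded bins.
#'
#' @param pairs LD pair table from [pairwiseLDScan()] (one population).
#' @param oeMatrix a VC-normalized [ContactMatrix-class].
#' @param binSize bin width (bp); defaults to the matrix bin size.
#' @param positions optional SNP positions (all MAF-passing SNPs) used to
#'   count zero-LD pairs; when NULL only stored pairs enter the percentile.
#' @param maxDist maximum bin-pair span (bp) retained in the track.
#' @param ldQuantile percentile summarizing r-squared per bin pair.
#' @return data.table: bin_i, bin_j (0-based), ld, oe.
#' @export
buildBinPairTrack <- function(pairs, oeMatrix, binSize = NULL,
                              positions = NULL, maxDist = 2e6,
                              ldQuantile = 0.75) {
  if (is.null(binSize)) binSize <- oeMatrix@binSize
  if (length(unique(pairs$population)) > 1)
    stop("supply a single population's pair table")
  nb <- nBins(oeMatrix)
  oe <- observedOverExpected(oeMatrix)
  maxSep <- as.integer(maxDist %/% binSize)
  pr <- as.data.table(pairs)
  pr <- pr[, .(bi = pmin((pos_i - 1L) %/% binSize, (pos_j - 1L) %/% binSize),
               bj = pmax((pos_i - 1L) %/% binSize, (pos_j - 1L) %/% binSize),
               r2 = r2)]
  pr <- pr[bi != bj & bj - bi <= maxSep]
  if (!is.null(positions)) {
    # total spanning SNP-pair count per bin pair, to restore floor-zeros
    pb <- (sort(positions) - 1L) %/% binSize
    cntPerBin <- table(factor(pb, levels = 0:(nb - 1L)))
    nz <- which(cntPerBin > 0) - 1L
    grid <- CJ(bi = nz, bj = nz)[bj > bi & bj - bi <= maxSep]
    grid[, nSpan := as.integer(cntPerBin[bi + 1L]) *
                     as.integer(cntPerBin[bj + 1L])]
    stored <- pr[order(r2), .(r2s = list(r2)), by = .(bi, bj)]
    grid <- merge(grid, stored, by = c("bi", "bj"), all.x = TRUE)
    # type-7 quantile of (nZero zeros, then sorted positive values),
    # without materializing the zeros
    qz <- function(sorted, nZero, q) {
      tot <- nZero + length(sorted)
      h <- (tot - 1) * q
      lo <- floor(h) + 1
      at <- function(k) if (k <= nZero) 0 else sorted[k - nZero]
      v1 <- at(lo)
      if (lo >= tot) return(v1)
      v1 + (h - floor(h)) * (at(lo + 1) - v1)
    }
    grid[, ld := vapply(seq_len(.N), function(r) {
      v <- r2s[[r]]
      if (is.null(v)) v <- numeric()
      qz(v, max(0L, nSpan[r] - length(v)), ldQuantile)
    }, 0)]
    ldTab <- grid[, .(bi, bj, ld)]
  } else {
    ldTab <- pr[, .(ld = as.numeric(quantile(r2, ldQuantile,
                                             names = FALSE))),
                by = .(bi, bj)]
  }
  incl <- which(includedBins(oeMatrix)) - 1L
  cj <- CJ(bi = incl, bj = incl)[bj > bi & bj - bi <= maxSep]
  oeTab <- merge(cj, oe[, .(bi = bin_i, bj = bin_j, oe = oe)],
                 by = c("bi", "bj"), all.x = TRUE)
  oeTab[is.na(oe), oe := 0]
  track <- merge(ldTab, oeTab, by = c("bi", "bj"), all = TRUE)
  track <- track[!(is.na(ld) & is.na(oe))]
  data.table::setnames(track, c("bi", "bj"), c("bin_i", "bin_j"))
  data.table::setattr(track, "binSize", as.integer(binSize))
  track[]
}

#' Multi-scale concordance of strong LD and frequent contacts
#'
#' For each window size, the chromosome is partitioned into consecutive
#' non-overlapping windows and all bin pairs with both bins in the same
#' window (and both an LD summary and a contact value) are collected. The
#' strong-LD mask is \code{ld > ldThresh}; the frequent-contact mask marks
#' contact values above the \code{contactPct} percentile computed over the
#' collected pairs of that analysis. Observed concordance is the fraction
#' with both flags. The expected value under no association is either the
#' product of the marginal rates (\code{expected = "product"}, the plain
#' independence reference) or the distance-stratified product
#' (\code{expected = "stratified"}, equivalent to averaging over random
#' reassignments of contact values among bin pairs at the same separation,
#' which controls for the shared dependence of both measures on genomic
#' distance).
#'
#' @param track bin-pair track from [buildBinPairTrack()].
#' @param windowSizes window widths in bp (default 5 kb to 1280 kb by
#'   doubling).
#' @param ldThresh strong-LD threshold on the bin-pair summary.
#' @param contactPct percentile (0-100) defining frequent contacts.
#' @param expected reference construction, see Details.
#' @return data.table: window_size, n_pairs, observed, expected.
#' @export
concordanceByWindow <- function(track,
                                windowSizes = c(5, 10, 20, 40, 80, 160,
                                                320, 640, 1280) * 1000,
                                ldThresh = 0.8, contactPct = 75,
                                expected = c("product", "stratified")) {
  expected <- match.arg(expected)
  binSize <- attr(track, "binSize")
  if (is.null(binSize)) stop("track lacks its binSize attribute")
  if (any(windowSizes < binSize))
    stop("window sizes must be at least one bin")
  if (!nrow(track)) stop("empty track")
  out <- lapply(windowSizes, function(w) {
    nbw <- w %/% binSize
    tt <- track[!is.na(ld) & !is.na(oe)]
    tt <- tt[bin_i %/% nbw == bin_j %/% nbw]
    if (!nrow(tt))
      return(data.table(window_size = w, n_pairs = 0L,
                        observed = NA_real_, expected = NA_real_))
    thr <- quantile(tt$oe, contactPct / 100, names = FALSE)
    tt[, strong := ld > ldThresh]
    tt[, freq := oe > thr]
    obs <- mean(tt$strong & tt$freq)
    exp_ <- if (expected == "product") {
      mean(tt$strong) * mean(tt$freq)
    } else {
      st <- tt[, .(pl = mean(strong), pc = mean(freq), n = .N),
               by = .(d = bin_j - bin_i)]
      sum(st$n * st$pl * st$pc) / sum(st$n)
    }
    data.table(window_size = w, n_pairs = nrow(tt), observed = obs,
               expected = exp_)
  })
  data.table::rbindlist(out)
}

#' Distance-decay profiles of LD and contact frequency
#'
#' Summarizes the nonzero values of each measure per distance bin and
#' reports the Spearman rank correlation of each measure with genomic
#' distance over the raw (unbinned) nonzero values, the standard way of
#' quantifying how fast each map decays along the chromosome.
#'
#' @param pairs LD pair table (one population).
#' @param x a VC-normalized [ContactMatrix-class]; normalized counts are
#'   the contact measure.
#' @param maxDist maximum distance (bp).
#' @param distBins number of equal-width distance bins for the summary
#'   table.
#' @return List with \code{profile} (distance bin, median r2, mean
#'   contact) and \code{spearman} (named rho for ld and contact).
#' @export
decayProfile <- function(pairs, x, maxDist = 2e6, distBins = 40L) {
  if (!isNormalized(x)) stop("run vcNormalize() first")
  tri <- methods::as(methods::as(x@normCounts, "TsparseMatrix"),
                     "generalMatrix")
  cd <- (tri@j - tri@i) * x@binSize
  keep <- cd > 0 & cd <= maxDist & tri@x > 0
  contact <- data.table(distance = cd[keep], value = tri@x[keep])
  ld <- as.data.table(pairs)[distance <= maxDist & r2 > 0,
                             .(distance, value = r2)]
  brk <- seq(0, maxDist, length.out = distBins + 1L)
  cut2 <- function(d) pmin(findInterval(d, brk, left.open = TRUE),
                           distBins)
  prof <- merge(
    ld[, .(median_r2 = median(value), n_ld = .N), by = .(bin = cut2(distance))],
    contact[, .(mean_contact = mean(value), n_contact = .N),
            by = .(bin = cut2(distance))],
    by = "bin", all = TRUE)
  prof[, dist_lo := brk[bin]]
  prof[, dist_hi := brk[bin + 1L]]
  sp <- function(d, v) {
    if (length(v) < 2 || stats::sd(v) == 0 || stats::sd(d) == 0)
      return(0)  # no monotone association among constant values
    cor(d, v, method = "spearman")
  }
  rho <- c(ld = sp(ld$distance, ld$value),
           contact = sp(contact$distance, contact$value))
  list(profile = prof[order(bin)], spearman = rho)
}

#' LD blocks spanned by each interaction
#'
#' Counts the blocks wholly contained in the open interval between the two
#' anchor midpoints of each interaction, quantifying how many haplotype
#' blocks a chromatin contact jumps across.
#'
#' @param interactions an [InteractionTrack-class].
#' @param blocks block table from [callLDBlocks()].
#' @return Integer vector, one count per interaction.
#' @export
blocksSpanned <- function(interactions, blocks) {
  m1 <- (start(anchorOne(interactions)) - 1 +
           end(anchorOne(interactions))) / 2
  m2 <- (start(anchorTwo(interactions)) - 1 +
           end(anchorTwo(interactions))) / 2
  vapply(seq_along(m1), function(k)
    sum(blocks$start > m1[k] & blocks$end < m2[k]), 0L)
}
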