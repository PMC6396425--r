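#' Boundary set from intervals
#'
#' Collapses a set of intervals (contact domains or LD blocks) to the
#' sorted, deduplicated point coordinates of their edges, the
#' representation on which boundary-distance statistics operate.
#'
#' @param starts,ends interval edge coordinates (bp), or a block/domain
#'   table with \code{start}/\code{end} columns passed as \code{starts}.
#' @return Sorted numeric vector of boundary positions.
#' @export
boundarySet <- function(starts, ends = NULL) {
  if (is.data.frame(starts)) {
    ends <- starts$end
    starts <- starts$start
  }
  sort(unique(c(starts, ends)))
}

#' Distance from each domain boundary to the nearest block boundary
#'
#' @param domainBoundaries,blockBoundaries sorted boundary positions (from
#'   [boundarySet()]).
#' @return List with \code{distances} (per domain boundary) and
#'   \code{median}.
#' @export
nearestBoundaryDistances <- function(domainBoundaries, blockBoundaries) {
  if (!length(blockBoundaries)) stop("empty block boundary set")
  if (!length(domainBoundaries)) stop("empty domain boundary set")
  b <- sort(blockBoundaries)
  k <- findInterval(domainBoundaries, b)
  lo <- b[pmax(k, 1L)]
  hi <- b[pmin(k + 1L, length(b))]
  d <- pmin(abs(domainBoundaries - lo), abs(hi - domainBoundaries))
  list(distances = d, median = median(d))
}

#' Uniform length-preserving permutation of block locations
#'
#' Places the blocks (lengths and count preserved, order randomized) at
#' uniform positions along the chromosome without overlap, by sequential
#' rejection. An alternative \code{mode = "rotate"} applies a single
#' circular shift, preserving inter-block gaps as well.
#'
#' @param blocks block table (needs \code{start}, \code{end}).
#' @param chromLength chromosome length (bp).
#' @param seed integer seed.
#' @param mode "uniform" (default) or "rotate".
#' @param maxAttempts placement attempts per block before giving up.
#' @return data.table with permuted \code{start}, \code{end} (other
#'   columns dropped), sorted by start.
#' @export
permuteBlocks <- function(blocks, chromLength, seed,
                          mode = c("uniform", "rotate"),
                          maxAttempts = 1000L) {
  mode <- match.arg(mode)
  len <- blocks$end - blocks$start
  if (sum(len) >= chromLength)
    stop("total block length must be below chromLength")
  withSeed(seed + 83L, {
    if (mode == "rotate") {
      shift <- sample.int(chromLength, 1L)
      s <- (blocks$start + shift) %% chromLength
      e <- s + len
      wrap <- e > chromLength
      s[wrap] <- s[wrap] - chromLength
      e[wrap] <- e[wrap] - chromLength
      out <- data.table(start = s, end = e)
      return(out[order(start)])
    }
    ord <- sample.int(length(len))
    placedS <- numeric(0); placedE <- numeric(0)
    for (l in len[ord]) {
      ok <- FALSE
      for (a in seq_len(maxAttempts)) {
        s <- sample.int(chromLength - l, 1L)
        e <- s + l
        if (!length(placedS) || all(e <= placedS | s >= placedE)) {
          placedS <- c(placedS, s); placedE <- c(placedE, e)
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("failed to place a permuted block of length ", l,
             " after ", maxAttempts, " attempts (blocks too dense)")
    }
    data.table(start = placedS, end = placedE)[order(start)]
  })
}

#' Permutation test for boundary coincidence or avoidance
#'
#' Compares the observed median distance between domain boundaries and
#' their nearest LD-block boundary to the distribution of medians after
#' permuting block locations. The one-sided p-value uses the add-one rule,
#' \eqn{p = (1 + \#\{\mathrm{null\ at\ least\ as\ extreme}\}) /
#' (n_{perm} + 1)}, so p is never 0. Direction "longer" tests whether block
#' boundaries avoid domain boundaries (the observed median is longer than
#' expected); "shorter" tests coincidence.
#'
#' @param domainBoundaries sorted domain boundary positions.
#' @param blocks block table.
#' @param chromLength chromosome length (bp).
#' @param nPerm number of permutations (>= 100).
#' @param alternative "longer" or "shorter".
#' @param seed integer seed.
#' @param mode permutation mode, see [permuteBlocks()].
#' @return List: observedMedian, nullMedians, p.
#' @export
boundaryPermutationTest <- function(domainBoundaries, blocks, chromLength,
                                    nPerm = 1000L,
                                    alternative = c("longer", "shorter"),
                                    seed = 1L, mode = "uniform") {
  alternative <- match.arg(alternative)
  if (nPerm < 100L) stop("nPerm must be at least 100")
  obs <- nearestBoundaryDistances(domainBoundaries,
                                  boundarySet(blocks))$median
  subSeeds <- withSeed(seed + 13L,
                       sample.int(.Machine$integer.max - 1000L, nPerm))
  nulls <- vapply(seq_len(nPerm), function(b) {
    pb <- permuteBlocks(blocks, chromLength, seed = subSeeds[b], mode = mode)
    nearestBoundaryDistances(domainBoundaries, boundarySet(pb))$median
  }, 0)
  extreme <- if (alternative == "longer") sum(nulls >= obs)
             else sum(nulls <= obs)
  list(observedMedian = obs, nullMedians = nulls,
       p = (1 + extreme) / (nPerm + 1))
}

#' Block length versus distance to the nearest domain boundary
#'
#' Assigns each block the distance from its midpoint to the nearest domain
#' boundary and summarizes the block-length distribution (median and
#' quartiles) per distance bin, profiling whether long blocks concentrate
#' at or away from chromatin boundaries.
#'
#' @param blocks block table.
#' @param domainBoundaries sorted domain boundary positions.
#' @param nBins number of quantile distance bins.
#' @return data.table: bin, dist_lo, dist_hi, n, median_length, q25, q75.
#' @export
blockLengthVsBoundaryDistance <- function(blocks, domainBoundaries,
                                          nBins = 5L) {
  if (!nrow(blocks) || !length(domainBoundaries)) stop("non-empty inputs required")
  mids <- (blocks$start + blocks$end) / 2
  d <- nearestBoundaryDistances(mids, domainBoundaries)$distances
  len <- blocks$end - blocks$start
  edges <- unique(quantile(d, seq(0, 1, length.out = nBins + 1L),
                           names = FALSE))
  bin <- pmax(pmin(findInterval(d, edges, left.open = TRUE),
                   length(edges) - 1L), 1L)
  dt <- data.table(bin = bin, d = d, len = len)
  out <- dt[, .(n = .N, median_length = median(len),
                q25 = quantile(len, 0.25, names = FALSE),
                q75 = quantile(len, 0.75, names = FALSE)),
            by = bin][order(bin)]
  out[, dist_lo := edges[bin]]
  out[, dist_hi := edges[bin + 1L]]
  out[]
}
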