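#' Two-locus haplotype counts
#'
#' Tallies the four haplotype classes (AB, Ab, aB, ab, with "A"/"B" the
#' allele coded 1 at each locus) over all haplotypes of a panel.
#'
#' @param panel a [HaplotypePanel-class].
#' @param i,j SNP column indices (distinct, in range).
#' @return Named numeric vector \code{c(nAB, nAb, naB, nab)}.
#' @examples
#' p <- HaplotypePanel(rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 0)),
#'                     positions = c(10L, 20L))
#' twoLocusCounts(p, 1, 2)
#' @export
twoLocusCounts <- function(panel, i, j) {
  ns <- nSnps(panel)
  if (i == j || i < 1 || j < 1 || i > ns || j > ns)
    stop("SNP indices must be distinct and within 1..", ns)
  a <- panel@alleles[, i]
  b <- panel@alleles[, j]
  c(nAB = sum(a == 1 & b == 1), nAb = sum(a == 1 & b == 0),
    naB = sum(a == 0 & b == 1), nab = sum(a == 0 & b == 0))
}

#' r-squared and D-prime from two-locus haplotype counts
#'
#' Definitional LD statistics: with haplotype frequency \eqn{p_{AB}} and
#' allele frequencies \eqn{p_A}, \eqn{p_B}, the coefficient
#' \eqn{D = p_{AB} - p_A p_B}, \eqn{r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))}, and
#' \eqn{D' = |D| / D_{max}} where \eqn{D_{max}} is the bound imposed by the
#' allele frequencies given the sign of D. Both statistics are clipped to
#' \[0, 1\] against floating-point rounding.
#'
#' @param counts numeric vector \code{(nAB, nAb, naB, nab)} as returned by
#'   [twoLocusCounts()].
#' @return Named numeric vector \code{c(r2, dprime)}.
#' @examples
#' r2Dprime(c(40, 10, 10, 40))  # r2 = 0.36, dprime = 0.6
#' @export
r2Dprime <- function(counts) {
  n <- sum(counts)
  if (n <= 0) stop("total haplotype count must be positive")
  pAB <- counts[[1]] / n
  pA <- (counts[[1]] + counts[[2]]) / n
  pB <- (counts[[1]] + counts[[3]]) / n
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("monomorphic locus: both loci must be polymorphic (pre-filter by MAF)")
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else        min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (dmax == 0) 0 else abs(D) / dmax
  c(r2 = min(max(r2, 0), 1), dprime = min(max(dprime, 0), 1))
}

#' EM haplotype-frequency estimation for unphased two-locus genotypes
#'
#' Estimates the four two-locus haplotype frequencies from a 3x3 table of
#' unphased genotype counts (rows: copies of allele A at locus 1 = 0,1,2;
#' columns likewise for locus 2). Only double heterozygotes are
#' phase-ambiguous; the E-step splits them between the AB/ab and Ab/aB
#' resolutions in proportion to the current frequency products. The
#' symmetric starting point (0.25 each) is a fixed point when the data are
#' all double heterozygotes, a documented degenerate case.
#'
#' @param genotypeTable 3x3 matrix of genotype counts.
#' @param tol convergence tolerance on the max frequency change.
#' @param maxIter iteration cap.
#' @return List with \code{freqs} (named pAB, pAb, paB, pab) and
#'   \code{iterations}.
#' @export
emHaplotypeFreqs <- function(genotypeTable, tol = 1e-10, maxIter = 1000L) {
  g <- as.matrix(genotypeTable)
  stopifnot(all(dim(g) == c(3, 3)))
  n2 <- 2 * sum(g)
  if (n2 <= 0) stop("total genotype count must be positive")
  # unambiguous haplotype contributions; g[i+1, j+1] = count of genotype (i, j)
  baseAB <- 2 * g[3, 3] + g[3, 2] + g[2, 3]
  baseAb <- 2 * g[3, 1] + g[3, 2] + g[2, 1]
  baseaB <- 2 * g[1, 3] + g[1, 2] + g[2, 3]
  baseab <- 2 * g[1, 1] + g[1, 2] + g[2, 1]
  dh <- g[2, 2]
  p <- rep(0.25, 4)  # pAB, pAb, paB, pab
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- p[1] * p[4] + p[2] * p[3]
    wCoupling <- if (denom > 0) p[1] * p[4] / denom else 0.5
    pNew <- c(baseAB + dh * wCoupling, baseAb + dh * (1 - wCoupling),
              baseaB + dh * (1 - wCoupling), baseab + dh * wCoupling) / n2
    delta <- max(abs(pNew - p))
    p <- pNew
    if (delta < tol) break
    if (iter >= maxIter)
      stop("EM did not converge after ", maxIter,
           " iterations; last estimate: ",
           paste(signif(p, 6), collapse = ", "))
  }
  list(freqs = c(pAB = p[1], pAb = p[2], paB = p[3], pab = p[4]),
       iterations = iter)
}

#' Likelihood-grid confidence interval for |D'|
#'
#' With allele frequencies fixed at their maximum-likelihood estimates and
#' the sign of D fixed at its point estimate, the multinomial likelihood of
#' the observed haplotype counts is evaluated on a grid of |D'| values over
#' \[0, 1\] and normalized to unit mass. The lower bound is the smallest grid
#' value accumulating \code{tailMass} of probability; the upper bound is the
#' largest grid value whose upper tail holds at least \code{tailMass}. These
#' are the one-sided 5\%/95\% bounds conventional in confidence-interval
#' (Gabriel-style) haplotype-block calling.
#'
#' @param counts haplotype counts \code{(nAB, nAb, naB, nab)}.
#' @param gridStep grid resolution on |D'|.
#' @param tailMass tail probability for each bound.
#' @return Named numeric \code{c(ciLow, ciHigh)}.
#' @export
dprimeCI <- function(counts, gridStep = 0.001, tailMass = 0.05) {
  n <- sum(counts)
  pA <- (counts[[1]] + counts[[2]]) / n
  pB <- (counts[[1]] + counts[[3]]) / n
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("monomorphic locus: both loci must be polymorphic")
  D <- counts[[1]] / n - pA * pB
  s <- if (D >= 0) 1 else -1
  dmax <- if (s > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else       min(pA * pB, (1 - pA) * (1 - pB))
  grid <- seq(0, 1, by = gridStep)
  Dg <- s * grid * dmax
  f <- rbind(pA * pB + Dg, pA * (1 - pB) - Dg,
             (1 - pA) * pB - Dg, (1 - pA) * (1 - pB) + Dg)
  f[f < 0 & f > -1e-12] <- 0
  ll <- colSums(as.vector(counts) * log(pmax(f, 1e-300)))
  w <- exp(ll - max(ll))
  tot <- sum(w)
  if (tot == 0 || !is.finite(tot)) stop("degenerate likelihood")
  cum <- cumsum(w) / tot
  upper <- rev(cumsum(rev(w))) / tot
  ciLow <- grid[which(cum >= tailMass)[1]]
  ciHigh <- grid[max(which(upper >= tailMass))]
  c(ciLow = ciLow, ciHigh = ciHigh)
}

# chunked, vectorized version of dprimeCI over many pairs; same grid
# construction, evaluated as (grid x pair) matrices
dprimeCIBatch <- function(cAB, nA, nB, nHap, gridStep = 0.002,
                          tailMass = 0.05, chunk = 2000L) {
  nPair <- length(cAB)
  grid <- seq(0, 1, by = gridStep)
  G <- length(grid)
  low <- numeric(nPair); high <- numeric(nPair)
  for (from in seq(1L, nPair, by = chunk)) {
    to <- min(from + chunk - 1L, nPair)
    sel <- from:to
    pA <- nA[sel] / nHap; pB <- nB[sel] / nHap
    D <- cAB[sel] / nHap - pA * pB
    s <- ifelse(D >= 0, 1, -1)
    dmax <- ifelse(s > 0, pmin(pA * (1 - pB), (1 - pA) * pB),
                   pmin(pA * pB, (1 - pA) * (1 - pB)))
    Dg <- outer(grid, s * dmax)                     # G x P
    f1 <- sweep(Dg, 2, pA * pB, "+")
    f2 <- sweep(-Dg, 2, pA * (1 - pB), "+")
    f3 <- sweep(-Dg, 2, (1 - pA) * pB, "+")
    f4 <- sweep(Dg, 2, (1 - pA) * (1 - pB), "+")
    cl <- function(m) log(pmax(m, 1e-300))
    c1 <- cAB[sel]; c2 <- nA[sel] - c1; c3 <- nB[sel] - c1
    c4 <- nHap - nA[sel] - nB[sel] + c1
    ll <- sweep(cl(f1), 2, c1, "*") + sweep(cl(f2), 2, c2, "*") +
          sweep(cl(f3), 2, c3, "*") + sweep(cl(f4), 2, c4, "*")
    w <- exp(sweep(ll, 2, apply(ll, 2, max), "-"))
    cum <- apply(w, 2, cumsum)
    tot <- cum[G, ]
    t_ <- tailMass * tot
    iLow <- colSums(cum < rep(t_, each = G)) + 1L
    upperMass <- sweep(-cum, 2, tot, "+") + w      # mass from i to end
    iHigh <- colSums(upperMass >= rep(t_, each = G))
    low[sel] <- grid[pmin(iLow, G)]
    high[sel] <- grid[pmax(iHigh, 1L)]
  }
  list(low = low, high = high)
}

# all-pairs r2/dprime among SNP columns of a 0/1 matrix, via crossproducts;
# returns list of matrices (upper triangles meaningful)
pairwiseLDMatrices <- function(alleles) {
  nHap <- nrow(alleles)
  p <- colMeans(alleles)
  pAB <- crossprod(alleles) / nHap
  D <- as.matrix(pAB) - outer(p, p)
  denom <- outer(p * (1 - p), p * (1 - p))
  r2 <- ifelse(denom > 0, D^2 / denom, NA_real_)
  pmat <- outer(p, rep(1, length(p)))
  qmat <- t(pmat)
  dmaxPos <- pmin(pmat * (1 - qmat), (1 - pmat) * qmat)
  dmaxNeg <- pmin(pmat * qmat, (1 - pmat) * (1 - qmat))
  dmax <- ifelse(D >= 0, dmaxPos, dmaxNeg)
  dprime <- ifelse(dmax > 0, abs(D) / dmax, 0)
  list(r2 = pmin(pmax(r2, 0), 1), dprime = pmin(pmax(dprime, 0), 1))
}

#' Pairwise LD scan over a haplotype panel
#'
#' Computes r-squared and D-prime for every ordered SNP pair within
#' \code{maxDist} among SNPs passing the MAF filter, separately per
#' population when more than one is present. Pairs with r-squared below
#' \code{r2Floor} are omitted from storage and are treated as zero by every
#' downstream consumer, mirroring the storage convention of large-scale LD
#' scans (default floor 1\%).
#'
#' @param panel a [HaplotypePanel-class].
#' @param mafMin minimum minor-allele frequency (default 0.05).
#' @param maxDist maximum pair distance in bp (default 2 Mb).
#' @param r2Floor storage floor on r-squared (default 0.01).
#' @return A data.table with columns pos_i, pos_j, r2, dprime, distance,
#'   population (pos_i < pos_j).
#' @export
pairwiseLDScan <- function(panel, mafMin = 0.05, maxDist = 2e6,
                           r2Floor = 0.01) {
  if (nSnps(panel) == 0) stop("empty panel")
  pops <- unique(panel@samplePopulation)
  out <- vector("list", length(pops))
  hapPop <- rep(panel@samplePopulation, each = 2L)
  for (k in seq_along(pops)) {
    al <- panel@alleles[hapPop == pops[k], , drop = FALSE]
    f <- colMeans(al)
    keep <- pmin(f, 1 - f) >= mafMin
    if (sum(keep) < 2) next
    al <- al[, keep, drop = FALSE]
    pos <- panel@positions[keep]
    nHap <- nrow(al)
    m <- ncol(al)
    p <- colMeans(al)
    D <- as.matrix(crossprod(al)) / nHap - outer(p, p)
    r2 <- D^2 / outer(p * (1 - p), p * (1 - p))
    # banded upper triangle within maxDist, r2 at or above the floor
    ut <- upper.tri(r2)
    sel <- which(ut & r2 >= r2Floor)
    ii <- (sel - 1L) %% m + 1L
    jj <- (sel - 1L) %/% m + 1L
    dist <- pos[jj] - pos[ii]
    ok <- dist <= maxDist
    ii <- ii[ok]; jj <- jj[ok]; dist <- dist[ok]
    Dv <- D[cbind(ii, jj)]
    pA <- p[ii]; pB <- p[jj]
    dmax <- ifelse(Dv >= 0, pmin(pA * (1 - pB), (1 - pA) * pB),
                   pmin(pA * pB, (1 - pA) * (1 - pB)))
    dprime <- ifelse(dmax > 0, pmin(abs(Dv) / dmax, 1), 0)
    out[[k]] <- data.table(
      pos_i = pos[ii], pos_j = pos[jj],
      r2 = pmin(r2[cbind(ii, jj)], 1), dprime = dprime,
      distance = dist, population = pops[k])
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0) {
    warning("no SNP pair passed the MAF, distance and r2 filters")
    res <- data.table(pos_i = integer(), pos_j = integer(), r2 = numeric(),
                      dprime = numeric(), distance = integer(),
                      population = character())
  }
  setkey(res, population, pos_i, pos_j)
  res[]
}

#' Call haplotype blocks with the confidence-interval criterion
#'
#' Implements the D-prime confidence-interval block definition: each SNP
#' pair within \code{maxSpan} is classified as "strong LD" (CI lower bound
#' at least \code{strongLow} and upper bound at least \code{strongHigh}),
#' "strong recombination" (CI upper bound below \code{recombHigh}), or
#' uninformative. A
#' candidate block (i..j) requires its outermost pair to be in strong LD and
#' the fraction strong / (strong + recombination) over informative inner
#' pairs to reach \code{informFrac}. Candidates are accepted greedily by bp
#' span (ties: leftmost first), skipping overlaps; the small-block span caps
#' of some implementations are deliberately disabled. Monomorphic-by-MAF
#' SNPs are removed before classification.
#'
#' @param panel a [HaplotypePanel-class] (one population; for several, call
#'   per population subset).
#' @param strongLow,strongHigh,recombHigh CI thresholds (defaults 0.70,
#'   0.98, 0.90).
#' @param informFrac required strong fraction among informative pairs
#'   (default 0.95).
#' @param maxSpan maximum block span in bp (default 2 Mb).
#' @param mafMin MAF filter applied before classification.
#' @param gridStep grid resolution of the D' likelihood grid used for
#'   classification (coarser than the single-pair default; the thresholds
#'   lie on the grid).
#' @return data.table of blocks: chrom, start, end (1-based, outermost SNP
#'   positions), n_snps, population; sorted by start.
#' @export
callLDBlocks <- function(panel, strongLow = 0.70, strongHigh = 0.98,
                         recombHigh = 0.90, informFrac = 0.95,
                         maxSpan = 2e6, mafMin = 0.05, gridStep = 0.002) {
  pops <- unique(panel@samplePopulation)
  hapPop <- rep(panel@samplePopulation, each = 2L)
  res <- list()
  for (pop in pops) {
    al <- panel@alleles[hapPop == pop, , drop = FALSE]
    f <- colMeans(al)
    keep <- pmin(f, 1 - f) >= mafMin
    if (sum(keep) < 2) next
    al <- al[, keep, drop = FALSE]
    pos <- panel@positions[keep]
    n <- length(pos)
    # classify pairs within span by their D' CI (vectorized over pairs)
    strong <- matrix(0L, n, n)
    recomb <- matrix(0L, n, n)
    nHap <- nrow(al)
    cABm <- as.matrix(crossprod(al)) # raw counts of (1,1)
    nA <- colSums(al)
    idx <- which(upper.tri(cABm), arr.ind = TRUE)
    idx <- idx[pos[idx[, 2]] - pos[idx[, 1]] <= maxSpan, , drop = FALSE]
    if (nrow(idx)) {
      ci <- dprimeCIBatch(
        cAB = cABm[idx],
        nA = nA[idx[, 1]], nB = nA[idx[, 2]], nHap = nHap,
        gridStep = gridStep)
      isStrong <- ci$low >= strongLow & ci$high >= strongHigh
      isRecomb <- !isStrong & ci$high < recombHigh
      strong[idx[isStrong, , drop = FALSE]] <- 1L
      recomb[idx[isRecomb, , drop = FALSE]] <- 1L
    }
    # 2D prefix sums for O(1) window tallies
    cs <- function(m) {
      m <- apply(m, 2, cumsum)
      t(apply(m, 1, cumsum))
    }
    S <- cs(strong); R <- cs(recomb)
    rect <- function(C, i, j) {
      C[j, j] - (if (i > 1) C[i - 1, j] else 0) -
        (if (i > 1) C[j, i - 1] else 0) + (if (i > 1) C[i - 1, i - 1] else 0)
    }
    cand <- list()
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (pos[j] - pos[i] > maxSpan) break
        if (!strong[i, j]) next
        ns <- rect(S, i, j); nr <- rect(R, i, j)
        if (ns + nr > 0 && ns / (ns + nr) >= informFrac)
          cand[[length(cand) + 1L]] <- c(i, j)
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    span <- pos[cand[, 2]] - pos[cand[, 1]]
    ord <- order(-span, pos[cand[, 1]])
    used <- rep(FALSE, n)
    acc <- list()
    for (k in ord) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (any(used[i:j])) next
      used[i:j] <- TRUE
      acc[[length(acc) + 1L]] <- data.table(
        chrom = panel@chrom, start = pos[i], end = pos[j],
        n_snps = j - i + 1L, population = pop)
    }
    res[[pop]] <- data.table::rbindlist(acc)
  }
  out <- data.table::rbindlist(res)
  if (nrow(out)) {
    out <- out[order(population, start)]
  } else {
    out <- data.table(chrom = character(), start = integer(),
                      end = integer(), n_snps = integer(),
                      population = character())
  }
  out[]
}
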