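# Independent oracles and fixture builders shared across tests.
# Oracles are written from definitions, not by calling package internals.

# definitional r2 / D' from four haplotype counts
oracleR2Dprime <- function(nAB, nAb, naB, nab) {
  n <- nAB + nAb + naB + nab
  pAB <- nAB / n
  pA <- (nAB + nAb) / n
  pB <- (nAB + naB) / n
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else        min(pA * pB, (1 - pA) * (1 - pB))
  c(r2 = r2, dprime = if (dmax == 0) 0 else abs(D) / dmax)
}

# quadratic brute-force LD table: per-haplotype tallies and the
# definitional formulas, honoring MAF floor, distance cap and r2 floor
oracleLDTable <- function(alleles, positions, mafMin = 0.05,
                          maxDist = 2e6, r2Floor = 0.01) {
  f <- colMeans(alleles)
  keep <- pmin(f, 1 - f) >= mafMin
  al <- alleles[, keep, drop = FALSE]
  pos <- positions[keep]
  out <- list()
  for (i in seq_len(ncol(al) - 1L)) {
    for (j in (i + 1L):ncol(al)) {
      if (pos[j] - pos[i] > maxDist) break
      a <- al[, i]; b <- al[, j]
      st <- oracleR2Dprime(sum(a == 1 & b == 1), sum(a == 1 & b == 0),
                           sum(a == 0 & b == 1), sum(a == 0 & b == 0))
      if (st["r2"] >= r2Floor)
        out[[length(out) + 1L]] <- data.frame(
          pos_i = pos[i], pos_j = pos[j],
          r2 = min(st[["r2"]], 1), dprime = min(st[["dprime"]], 1))
    }
  }
  if (!length(out)) return(data.frame(pos_i = integer(), pos_j = integer(),
                                      r2 = numeric(), dprime = numeric()))
  do.call(rbind, out)
}

# random small panel
randomPanel <- function(seed, nHap = 40L, nSnp = 12L, spacing = 1000L) {
  set.seed(seed)
  al <- matrix(rbinom(nHap * nSnp, 1L, runif(nSnp, 0.2, 0.8)[
    rep(seq_len(nSnp), each = nHap)]), nHap, nSnp)
  HaplotypePanel(al, positions = seq_len(nSnp) * spacing)
}

# single-binary-covariate logistic regression via IRLS, written out
# explicitly as the reference for the 2x2 Wald odds ratio
irlsLogOr <- function(y, x, maxIter = 50L, tol = 1e-10) {
  X <- cbind(1, as.numeric(x))
  beta <- c(0, 0)
  for (it in seq_len(maxIter)) {
    eta <- X %*% beta
    mu <- 1 / (1 + exp(-eta))
    w <- as.vector(mu * (1 - mu))
    z <- eta + (y - mu) / w
    betaNew <- solve(t(X) %*% (w * X), t(X) %*% (w * z))
    if (max(abs(betaNew - beta)) < tol) return(as.vector(betaNew)[2])
    beta <- betaNew
  }
  as.vector(beta)[2]
}

# interaction track with n records at uniform positions, ~half significant
randomTrack <- function(seed, n = 200L, chromLength = 1e7,
                        anchorWidth = 5000L, sepRange = c(20000, 2000000)) {
  set.seed(seed)
  a1 <- sort(sample.int(chromLength - sepRange[2] - 2L * anchorWidth, n))
  sep <- round(runif(n, sepRange[1], sepRange[2]))
  InteractionTrack("chrS", a1, a1 + anchorWidth, a1 + sep,
                   a1 + sep + anchorWidth,
                   score = ifelse(runif(n) < 0.5, 5 + rexp(n),
                                  runif(n, 0, 4.9)))
}

# regular domain fixture on a 2.56-Mb chromosome
fixtureDomains <- function() {
  data.frame(start = seq(100000, 2400000, by = 250000),
             end = seq(180000, 2480000, by = 250000))
}

# blocks straddling every domain boundary plus small interior blocks;
# the boundary-avoiding fixture for the permutation test
fixtureStraddlingBlocks <- function(seed) {
  dom <- fixtureDomains()
  domB <- boundarySet(dom)
  straddle <- data.frame(start = domB - 25000, end = domB + 25000)
  set.seed(seed)
  small <- do.call(rbind, lapply(seq_len(nrow(dom)), function(d) {
    ctr <- (dom$start[d] + dom$end[d]) / 2
    s <- round(runif(3, ctr - 8000, ctr + 2000))
    data.frame(start = s, end = s + round(runif(3, 1500, 4000)))
  }))
  rbind(straddle, small)
}
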