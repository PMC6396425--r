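#' Vanilla-coverage (VC) normalization
#'
#' Divides every contact count by the product of its two bins' coverage
#' marginals (row + column sums of the symmetrized matrix, the "vanilla
#' coverage" vector), then rescales so the total normalized mass equals the
#' total raw mass. Bins with zero marginal are flagged excluded (NA in the
#' coverage vector) and drop from all downstream statistics rather than
#' being smoothed.
#'
#' @param x a [ContactMatrix-class] with at least one nonzero entry.
#' @return The matrix with \code{normCounts} and \code{normVector} filled.
#' @export
vcNormalize <- function(x) {
  cnt <- x@counts
  if (length(cnt@x) == 0 || sum(cnt@x) == 0)
    stop("all-zero contact matrix cannot be normalized")
  sym <- cnt + Matrix::t(cnt)
  Matrix::diag(sym) <- Matrix::diag(cnt)  # diagonal counted once
  v <- Matrix::rowSums(sym)
  excluded <- v == 0
  tri <- methods::as(methods::as(cnt, "TsparseMatrix"), "generalMatrix")
  i <- tri@i + 1L; j <- tri@j + 1L
  m <- tri@x / (v[i] * v[j])
  scale <- sum(tri@x) / sum(m)
  m <- m * scale
  norm <- methods::as(Matrix::sparseMatrix(i = i, j = j, x = m,
                                           dims = dim(cnt)), "CsparseMatrix")
  v[excluded] <- NA_real_
  methods::initialize(x, normCounts = norm, normVector = v,
                      expected = numeric())
}

#' Expected contact by genomic distance
#'
#' Mean normalized count over all included-bin pairs at each separation
#' \code{d = j - i} (in bins), with structural zeros between included bins
#' counted, matching the standard per-diagonal expected profile used for
#' observed/expected transforms. Set \code{nonzeroOnly = TRUE} to average
#' over stored (nonzero) entries instead.
#'
#' @param x a VC-normalized [ContactMatrix-class].
#' @param nonzeroOnly average over nonzero entries only.
#' @return Numeric vector of length \code{nBins(x)}; element d + 1 is the
#'   expected value at distance d (NA where no included pair exists).
#' @export
expectedByDistance <- function(x, nonzeroOnly = FALSE) {
  if (!isNormalized(x)) stop("run vcNormalize() first")
  nb <- x@nBins
  incl <- includedBins(x)
  tri <- methods::as(methods::as(x@normCounts, "TsparseMatrix"),
                     "generalMatrix")
  d <- tri@j - tri@i  # 0-based distance in bins
  sums <- rep(0, nb)
  t1 <- tapply(tri@x, d, sum)
  sums[as.integer(names(t1)) + 1L] <- t1
  if (nonzeroOnly) {
    cnts <- rep(0, nb)
    t2 <- tapply(tri@x, d, length)
    cnts[as.integer(names(t2)) + 1L] <- t2
  } else {
    # pairs (i, i+d) with both bins included, via a correlation of the
    # inclusion indicator
    iv <- as.numeric(incl)
    cnts <- vapply(0:(nb - 1L), function(dd)
      sum(iv[seq_len(nb - dd)] * iv[seq_len(nb - dd) + dd]), 0)
  }
  ifelse(cnts > 0, sums / cnts, NA_real_)
}

#' @describeIn expectedByDistance return the matrix with its expected
#'   profile stored (used by downstream transforms)
#' @export
computeExpected <- function(x, nonzeroOnly = FALSE) {
  methods::initialize(x, expected = expectedByDistance(x, nonzeroOnly))
}

#' Observed / expected transform
#'
#' Divides each normalized entry by the expected value at its distance.
#' Entries at distances whose expected value is zero or undefined are
#' omitted. By construction the mean O/E over each diagonal (zeros between
#' included bins counted) is exactly 1.
#'
#' @param x a VC-normalized [ContactMatrix-class]; the expected profile is
#'   computed if absent.
#' @return data.table of stored entries: bin_i, bin_j (0-based), distance
#'   (bins), oe.
#' @export
observedOverExpected <- function(x) {
  if (!isNormalized(x)) stop("run vcNormalize() first")
  if (!length(x@expected)) x <- computeExpected(x)
  tri <- methods::as(methods::as(x@normCounts, "TsparseMatrix"),
                     "generalMatrix")
  d <- tri@j - tri@i
  e <- x@expected[d + 1L]
  ok <- !is.na(e) & e > 0
  data.table(bin_i = tri@i[ok], bin_j = tri@j[ok], distance = d[ok],
             oe = tri@x[ok] / e[ok])
}
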