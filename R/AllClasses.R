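#' @importFrom methods new validObject setClass setGeneric setMethod is slot
#' @importFrom stats quantile median rbinom rpois rnorm runif rexp cor ks.test
#'   p.adjust dhyper qnorm pnorm sd rlnorm
#' @import Matrix
#' @importClassesFrom Matrix dgCMatrix
#' @importFrom IRanges IRanges findOverlaps start end width
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom data.table data.table as.data.table setkey setkeyv := .N .SD CJ
NULL

setClassUnion("matrixOrNull", c("matrix", "NULL"))

#' HaplotypePanel: phased biallelic haplotypes with coordinates
#'
#' A phased 0/1 haplotype matrix (rows are haplotypes, two consecutive rows
#' per diploid sample) over biallelic SNPs with strictly increasing 1-based
#' positions on a single chromosome. This is the source object for every LD
#' quantity in the package, mirroring the per-super-population panels of a
#' phased reference cohort.
#'
#' @slot alleles integer matrix in \{0,1\}; haplotypes x SNPs.
#' @slot positions integer vector, strictly increasing 1-based bp.
#' @slot chrom single chromosome label.
#' @slot samplePopulation population label per diploid sample
#'   (length \code{nrow(alleles)/2}).
#' @export
setClass("HaplotypePanel",
  representation(
    alleles = "matrix",
    positions = "integer",
    chrom = "character",
    samplePopulation = "character"
  )
)

setValidity("HaplotypePanel", function(object) {
  msg <- character()
  a <- object@alleles
  if (!is.numeric(a) || any(!(a %in% c(0L, 1L))))
    msg <- c(msg, "alleles must be a 0/1 matrix")
  if (nrow(a) %% 2L != 0L)
    msg <- c(msg, "haplotype count must be even (two per sample)")
  if (ncol(a) != length(object@positions))
    msg <- c(msg, "ncol(alleles) must equal length(positions)")
  if (length(object@positions) && any(diff(object@positions) <= 0L))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(object@positions) && any(object@positions < 1L))
    msg <- c(msg, "positions are 1-based and must be >= 1")
  if (length(object@chrom) != 1L)
    msg <- c(msg, "chrom must be a single label")
  if (length(object@samplePopulation) != nrow(a) / 2L)
    msg <- c(msg, "samplePopulation must have one label per diploid sample")
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypePanel
#'
#' @param alleles haplotype x SNP matrix of 0/1.
#' @param positions 1-based bp positions, strictly increasing.
#' @param chrom chromosome label.
#' @param samplePopulation population label per diploid sample; a scalar is
#'   recycled.
#' @return A [HaplotypePanel-class] object.
#' @examples
#' HaplotypePanel(matrix(c(0, 1, 1, 0), 2, 2), positions = c(100L, 200L))
#' @export
HaplotypePanel <- function(alleles, positions, chrom = "chrS",
                           samplePopulation = "POP1") {
  storage.mode(alleles) <- "integer"
  if (length(samplePopulation) == 1L)
    samplePopulation <- rep(samplePopulation, nrow(alleles) / 2L)
  new("HaplotypePanel", alleles = alleles, positions = as.integer(positions),
      chrom = chrom, samplePopulation = samplePopulation)
}

#' @describeIn HaplotypePanel number of haplotypes
#' @param panel,object a HaplotypePanel
#' @export
nHaplotypes <- function(panel) nrow(panel@alleles)

#' @describeIn HaplotypePanel number of SNPs
#' @export
nSnps <- function(panel) ncol(panel@alleles)

#' @describeIn HaplotypePanel SNP positions (1-based bp)
#' @export
snpPositions <- function(panel) panel@positions

#' @describeIn HaplotypePanel minor allele frequency per SNP
#' @export
mafs <- function(panel) {
  f <- colMeans(panel@alleles)
  pmin(f, 1 - f)
}

#' @describeIn HaplotypePanel per-sample population labels
#' @export
samplePopulations <- function(panel) panel@samplePopulation

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel:", nrow(object@alleles), "haplotypes x",
      ncol(object@alleles), "SNPs on", object@chrom, "\n")
  if (length(object@positions))
    cat("  positions:", min(object@positions), "-", max(object@positions),
        "bp; populations:",
        paste(unique(object@samplePopulation), collapse = ","), "\n")
})

#' ContactMatrix: binned intra-chromosomal contact counts
#'
#' Sparse upper-triangular contact counts for one chromosome at a fixed bin
#' size, together with (after [vcNormalize()]) a per-bin coverage vector,
#' normalized counts, and (after [expectedByDistance()]) the per-diagonal
#' expected profile used for observed/expected transforms. Bins with zero
#' coverage are flagged excluded and drop from all downstream statistics.
#'
#' @slot chrom chromosome label.
#' @slot binSize bin width in bp.
#' @slot nBins number of bins.
#' @slot counts raw counts, sparse upper-triangular (i <= j).
#' @slot normCounts VC-normalized counts (empty until [vcNormalize()]).
#' @slot normVector per-bin coverage marginal; NA for excluded bins
#'   (empty until normalized).
#' @slot expected per-diagonal mean normalized count (distance 0 ..
#'   nBins - 1; empty until computed).
#' @export
setClass("ContactMatrix",
  representation(
    chrom = "character",
    binSize = "integer",
    nBins = "integer",
    counts = "dgCMatrix",
    normCounts = "dgCMatrix",
    normVector = "numeric",
    expected = "numeric"
  )
)

setValidity("ContactMatrix", function(object) {
  msg <- character()
  if (object@binSize < 1L) msg <- c(msg, "binSize must be positive")
  if (nrow(object@counts) != object@nBins ||
      ncol(object@counts) != object@nBins)
    msg <- c(msg, "counts must be nBins x nBins")
  tl <- Matrix::tril(object@counts, -1)
  if (length(tl@x) && any(tl@x != 0))
    msg <- c(msg, "counts must be upper-triangular (i <= j)")
  if (any(object@counts@x < 0)) msg <- c(msg, "counts must be nonnegative")
  if (length(object@normVector) &&
      length(object@normVector) != object@nBins)
    msg <- c(msg, "normVector length must equal nBins")
  if (length(object@expected) && length(object@expected) != object@nBins)
    msg <- c(msg, "expected length must equal nBins")
  if (length(msg)) msg else TRUE
})

#' Construct a ContactMatrix from triplet entries
#'
#' Entries may be given in either triangle or both; they are symmetrized onto
#' the upper triangle taking the maximum where both orientations occur.
#'
#' @param binI,binJ 0-based bin indices.
#' @param count nonnegative counts.
#' @param nBins number of bins.
#' @param binSize bin width (bp).
#' @param chrom chromosome label.
#' @return A [ContactMatrix-class].
#' @export
ContactMatrix <- function(binI, binJ, count, nBins, binSize = 5000L,
                          chrom = "chrS") {
  i <- pmin(binI, binJ)
  j <- pmax(binI, binJ)
  m <- Matrix::sparseMatrix(i = i + 1L, j = j + 1L, x = count,
                            dims = c(nBins, nBins), use.last.ij = FALSE)
  # duplicated (i,j) pairs were summed by sparseMatrix; a full symmetric dump
  # therefore double-counts off-diagonals -- rebuild with max instead
  key <- paste(i, j)
  if (anyDuplicated(key)) {
    agg <- tapply(count, key, max)
    ij <- do.call(rbind, strsplit(names(agg), " "))
    m <- Matrix::sparseMatrix(i = as.integer(ij[, 1]) + 1L,
                              j = as.integer(ij[, 2]) + 1L,
                              x = as.numeric(agg), dims = c(nBins, nBins))
  }
  new("ContactMatrix", chrom = chrom, binSize = as.integer(binSize),
      nBins = as.integer(nBins), counts = methods::as(m, "CsparseMatrix"),
      normCounts = emptySparse(nBins), normVector = numeric(),
      expected = numeric())
}

emptySparse <- function(n) {
  methods::as(Matrix::sparseMatrix(i = integer(), j = integer(),
                                   x = numeric(), dims = c(n, n)),
              "CsparseMatrix")
}

#' @describeIn ContactMatrix number of bins
#' @param x a ContactMatrix
#' @export
nBins <- function(x) x@nBins

#' @describeIn ContactMatrix bin width in bp
#' @export
binSize <- function(x) x@binSize

#' @describeIn ContactMatrix raw counts (sparse upper triangle)
#' @export
rawCounts <- function(x) x@counts

#' @describeIn ContactMatrix normalized counts (after vcNormalize)
#' @export
normCounts <- function(x) {
  if (!isNormalized(x)) stop("matrix has not been normalized; run vcNormalize()")
  x@normCounts
}

#' @describeIn ContactMatrix per-bin coverage vector (NA = excluded bin)
#' @export
normVector <- function(x) x@normVector

#' @describeIn ContactMatrix TRUE once vcNormalize() has been applied
#' @export
isNormalized <- function(x) length(x@normVector) > 0L

#' @describeIn ContactMatrix logical vector of bins retained after
#'   normalization (all TRUE for an unnormalized matrix)
#' @export
includedBins <- function(x) {
  if (!isNormalized(x)) rep(TRUE, x@nBins) else !is.na(x@normVector)
}

setMethod("show", "ContactMatrix", function(object) {
  cat("ContactMatrix:", object@nBins, "bins of", object@binSize, "bp on",
      object@chrom, "\n  stored entries:", length(object@counts@x),
      "; total count:", sum(object@counts@x), "\n")
  if (isNormalized(object))
    cat("  VC-normalized;", sum(is.na(object@normVector)), "bins excluded\n")
  if (length(object@expected))
    cat("  expected-by-distance computed\n")
})

#' InteractionTrack: paired-anchor chromatin interaction records
#'
#' A set of intra-chromosomal interaction calls, each joining two anchor
#' intervals with a score, a significance flag and a midpoint-to-midpoint
#' distance. For promoter-capture records (\code{kind = "pchic"}) anchor 1 is
#' the bait (promoter) fragment and anchor 2 the promoter-interacting region
#' (PIR), and significance is score >= 5 (the conventional CHiCAGO cutoff).
#' Anchor coordinates are accepted as 0-based half-open intervals (the BEDPE
#' convention) and stored as IRanges.
#'
#' @slot chrom chromosome label.
#' @slot anchor1,anchor2 IRanges of anchor intervals (1-based closed
#'   internally; constructors convert from 0-based half-open).
#' @slot score numeric score per record.
#' @slot significant logical flag per record.
#' @slot distance midpoint separation in bp.
#' @slot kind "hic" or "pchic".
#' @export
setClass("InteractionTrack",
  representation(
    chrom = "character",
    anchor1 = "IRanges",
    anchor2 = "IRanges",
    score = "numeric",
    significant = "logical",
    distance = "numeric",
    kind = "character"
  )
)

setValidity("InteractionTrack", function(object) {
  msg <- character()
  n <- length(object@anchor1)
  if (length(object@anchor2) != n || length(object@score) != n ||
      length(object@significant) != n || length(object@distance) != n)
    msg <- c(msg, "all per-record slots must have equal length")
  if (!object@kind %in% c("hic", "pchic"))
    msg <- c(msg, "kind must be 'hic' or 'pchic'")
  if (n && any(start(object@anchor1) >= start(object@anchor2)))
    msg <- c(msg, "anchor1 must start before anchor2")
  if (object@kind == "pchic" && n &&
      any(object@significant != (object@score >= 5)))
    msg <- c(msg, "pchic significance must equal score >= 5")
  if (length(msg)) msg else TRUE
})

#' Construct an InteractionTrack
#'
#' @param chrom chromosome label.
#' @param a1Start,a1End,a2Start,a2End anchor coordinates, 0-based half-open
#'   (BEDPE convention). Anchor 1 must start before anchor 2; records are
#'   reoriented if needed.
#' @param score numeric scores.
#' @param kind "hic" or "pchic". For "pchic" the significance flag is derived
#'   as score >= 5; for "hic" it must be supplied.
#' @param significant logical flags (required for kind = "hic").
#' @return An [InteractionTrack-class].
#' @export
InteractionTrack <- function(chrom, a1Start, a1End, a2Start, a2End, score,
                             kind = c("pchic", "hic"), significant = NULL) {
  kind <- match.arg(kind)
  flip <- a1Start > a2Start
  if (any(flip)) {
    tmpS <- a1Start[flip]; tmpE <- a1End[flip]
    a1Start[flip] <- a2Start[flip]; a1End[flip] <- a2End[flip]
    a2Start[flip] <- tmpS; a2End[flip] <- tmpE
  }
  if (kind == "pchic") {
    significant <- score >= 5
  } else if (is.null(significant)) {
    stop("significant flags must be supplied for kind = 'hic'")
  }
  mid1 <- (a1Start + a1End) / 2
  mid2 <- (a2Start + a2End) / 2
  new("InteractionTrack", chrom = chrom,
      anchor1 = IRanges(start = a1Start + 1L, end = as.integer(a1End)),
      anchor2 = IRanges(start = a2Start + 1L, end = as.integer(a2End)),
      score = as.numeric(score), significant = as.logical(significant),
      distance = mid2 - mid1, kind = kind)
}

setMethod("length", "InteractionTrack", function(x) length(x@anchor1))

#' @describeIn InteractionTrack bait/left anchor as IRanges (1-based closed)
#' @param x an InteractionTrack
#' @export
anchorOne <- function(x) x@anchor1

#' @describeIn InteractionTrack PIR/right anchor as IRanges (1-based closed)
#' @export
anchorTwo <- function(x) x@anchor2

#' @describeIn InteractionTrack record scores
#' @export
interactionScores <- function(x) x@score

#' @describeIn InteractionTrack significance flags
#' @export
isSignificant <- function(x) x@significant

#' @describeIn InteractionTrack midpoint-to-midpoint distances (bp)
#' @export
interactionDistances <- function(x) x@distance

#' Subset an InteractionTrack by record index
#' @param x an InteractionTrack
#' @param idx integer or logical index
#' @return An InteractionTrack with the selected records.
#' @export
subsetInteractions <- function(x, idx) {
  new("InteractionTrack", chrom = x@chrom, anchor1 = x@anchor1[idx],
      anchor2 = x@anchor2[idx], score = x@score[idx],
      significant = x@significant[idx], distance = x@distance[idx],
      kind = x@kind)
}

#' Concatenate InteractionTracks on the same chromosome
#' @param ... InteractionTrack objects of the same kind and chromosome.
#' @return A combined InteractionTrack.
#' @export
bindInteractions <- function(...) {
  xs <- list(...)
  stopifnot(length(unique(vapply(xs, function(x) x@chrom, ""))) == 1L,
            length(unique(vapply(xs, function(x) x@kind, ""))) == 1L)
  new("InteractionTrack", chrom = xs[[1]]@chrom,
      anchor1 = do.call(c, lapply(xs, anchorOne)),
      anchor2 = do.call(c, lapply(xs, anchorTwo)),
      score = unlist(lapply(xs, interactionScores)),
      significant = unlist(lapply(xs, isSignificant)),
      distance = unlist(lapply(xs, interactionDistances)),
      kind = xs[[1]]@kind)
}

setMethod("show", "InteractionTrack", function(object) {
  cat("InteractionTrack (", object@kind, "): ", length(object),
      " records on ", object@chrom, "; ",
      sum(object@significant), " significant\n", sep = "")
})

# run an expression under a temporary RNG state, restoring the caller's
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
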