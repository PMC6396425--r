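#' Write a haplotype panel as VCF plus population panel TSV
#'
#' Emits a minimal single-chromosome VCF (phased GT, biallelic A/G records)
#' and the companion sample-to-population table, the input pair expected by
#' [readVcfPanel()].
#'
#' @param panel a [HaplotypePanel-class].
#' @param vcfPath,panelPath output paths.
#' @return Invisibly, the two paths.
#' @export
writeVcfPanel <- function(panel, vcfPath, panelPath) {
  nSamp <- nHaplotypes(panel) / 2L
  samples <- sprintf("S%04d", seq_len(nSamp))
  con <- file(vcfPath, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", panel@chrom, ">"),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t")), con)
  al <- panel@alleles
  for (k in seq_len(nSnps(panel))) {
    gt <- paste(al[seq(1, nrow(al), 2), k], al[seq(2, nrow(al), 2), k],
                sep = "|")
    writeLines(paste(c(panel@chrom, panel@positions[k],
                       sprintf("snp%d", k), "A", "G", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  utils::write.table(
    data.frame(sample = samples, super_population = panel@samplePopulation),
    panelPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vcfPath, panelPath))
}

#' Read a phased VCF and population panel into a HaplotypePanel
#'
#' Parses a single-chromosome VCF, keeping biallelic SNP records only
#' (others are skipped and counted), joins population labels from the
#' panel TSV, and preserves 1-based positions. Unphased genotypes raise an
#' error in strict mode.
#'
#' @param vcfPath,panelPath input paths.
#' @param strict error on unphased genotypes (default TRUE).
#' @return A [HaplotypePanel-class]; the number of skipped records is
#'   attached as attribute \code{"skipped"}.
#' @export
readVcfPanel <- function(vcfPath, panelPath, strict = TRUE) {
  v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1 &
    nchar(fix[, "ALT"]) == 1
  skipped <- sum(!biallelic)
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  if (strict && any(grepl("/", gt)))
    stop("unphased genotypes encountered in strict mode")
  panelTab <- utils::read.delim(panelPath, stringsAsFactors = FALSE)
  missing <- setdiff(colnames(gt), panelTab$sample)
  if (length(missing))
    stop("samples missing from panel file: ",
         paste(missing, collapse = ", "))
  pops <- panelTab$super_population[match(colnames(gt), panelTab$sample)]
  a1 <- apply(gt, 2, function(g) as.integer(substr(g, 1, 1)))
  a2 <- apply(gt, 2, function(g) as.integer(substr(g, 3, 3)))
  nSamp <- ncol(gt)
  alleles <- matrix(0L, 2L * nSamp, nrow(gt))
  alleles[seq(1, 2 * nSamp, 2), ] <- t(a1)
  alleles[seq(2, 2 * nSamp, 2), ] <- t(a2)
  pn <- HaplotypePanel(alleles,
                       positions = as.integer(fix[biallelic, "POS"]),
                       chrom = unique(fix[, "CHROM"])[1],
                       samplePopulation = pops)
  attr(pn, "skipped") <- skipped
  pn
}

#' Read / write interval BED files
#'
#' Intervals travel as standard BED (0-based half-open). [readBed()]
#' returns that convention unchanged; block tables (1-based inclusive of
#' the outermost SNPs) are converted on the way out by [writeBlocksBed()]
#' and back by [readBlocksBed()].
#'
#' @param path file path.
#' @param intervals data.frame with \code{start}, \code{end} (0-based
#'   half-open) and optionally \code{chrom}.
#' @param chrom chromosome label used when \code{intervals} lacks one.
#' @return \code{readBed}: data.table with chrom, start, end (0-based
#'   half-open).
#' @export
readBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

#' @rdname readBed
#' @export
writeBed <- function(intervals, path, chrom = "chrS") {
  ch <- if ("chrom" %in% names(intervals)) intervals$chrom else chrom
  gr <- GenomicRanges::GRanges(
    seqnames = ch,
    ranges = IRanges(start = intervals$start + 1L, end = intervals$end))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname readBed
#' @param blocks block table from [callLDBlocks()].
#' @export
writeBlocksBed <- function(blocks, path) {
  writeBed(data.table(chrom = blocks$chrom, start = blocks$start - 1L,
                      end = blocks$end), path)
}

#' @rdname readBed
#' @export
readBlocksBed <- function(path) {
  b <- readBed(path)
  data.table(chrom = b$chrom, start = b$start + 1L, end = b$end,
             n_snps = NA_integer_, population = NA_character_)
}

#' Read / write BEDPE interaction files
#'
#' The dialect is six anchor columns (0-based half-open), a name, the
#' score, then \code{significant} and \code{distance} columns. Round trips
#' are lossless up to float formatting.
#'
#' @param interactions an [InteractionTrack-class].
#' @param path file path.
#' @param kind interaction kind for the reader.
#' @param chromLength optional bound; coordinates beyond it are an error.
#' @return \code{readBedpe}: an [InteractionTrack-class].
#' @export
writeBedpe <- function(interactions, path) {
  n <- length(interactions)
  df <- data.frame(
    chrom1 = interactions@chrom,
    start1 = start(anchorOne(interactions)) - 1L,
    end1 = end(anchorOne(interactions)),
    chrom2 = interactions@chrom,
    start2 = start(anchorTwo(interactions)) - 1L,
    end2 = end(anchorTwo(interactions)),
    name = sprintf("int%d", seq_len(n)),
    score = interactionScores(interactions),
    significant = as.integer(isSignificant(interactions)),
    distance = interactionDistances(interactions))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeBedpe
#' @export
readBedpe <- function(path, kind = "pchic", chromLength = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 10L)
  if (length(bad))
    stop("malformed BEDPE line ", bad[1], ": expected 10 columns")
  m <- do.call(rbind, parts)
  s1 <- as.numeric(m[, 2]); e1 <- as.numeric(m[, 3])
  s2 <- as.numeric(m[, 5]); e2 <- as.numeric(m[, 6])
  if (anyNA(c(s1, e1, s2, e2)))
    stop("malformed BEDPE line ",
         which(is.na(s1 + e1 + s2 + e2))[1], ": non-numeric coordinates")
  if (!is.null(chromLength) && any(c(e1, e2) > chromLength))
    stop("coordinates exceed chromosome length")
  tr <- InteractionTrack(chrom = m[1, 1], a1Start = s1, a1End = e1,
                         a2Start = s2, a2End = e2,
                         score = as.numeric(m[, 8]), kind = kind,
                         significant = as.logical(as.integer(m[, 9])))
  tr
}

#' Read / write triplet-text contact matrices
#'
#' Plain-text sparse format: a header line
#' \code{#chrom=<label> bin_size=<bp> n_bins=<n>} followed by
#' tab-separated \code{bin_i bin_j count} rows (0-based bins). The reader
#' tolerates upper-triangular or full symmetric input, symmetrizing by
#' maximum.
#'
#' @param x a [ContactMatrix-class].
#' @param path file path.
#' @return \code{readTripletMatrix}: a [ContactMatrix-class] (raw counts
#'   only).
#' @export
writeTripletMatrix <- function(x, path) {
  tri <- methods::as(methods::as(x@counts, "TsparseMatrix"),
                     "generalMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#chrom=%s bin_size=%d n_bins=%d", x@chrom,
                     x@binSize, x@nBins), con)
  utils::write.table(data.frame(tri@i, tri@j, tri@x), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeTripletMatrix
#' @export
readTripletMatrix <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#"))
    stop("missing triplet header line (#chrom=... bin_size=... n_bins=...)")
  fields <- strsplit(sub("^#", "", hdr), " ")[[1]]
  kvs <- strsplit(fields, "=")
  vals <- stats::setNames(vapply(kvs, `[`, "", 2),
                          vapply(kvs, `[`, "", 1))
  dat <- utils::read.table(path, sep = "\t", skip = 1L,
                           col.names = c("i", "j", "x"))
  ContactMatrix(dat$i, dat$j, dat$x, nBins = as.integer(vals["n_bins"]),
                binSize = as.integer(vals["bin_size"]),
                chrom = vals["chrom"])
}
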