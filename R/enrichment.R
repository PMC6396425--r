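#' Gene annotation table
#'
#' Validates and assembles the gene annotation used by the enrichment
#' analyses: per gene a TSS (1-based point), a promoter interval and an
#' optional capture bait fragment, all 0-based half-open on one chromosome.
#'
#' @param gene_id gene identifiers (unique).
#' @param tss transcription start sites (1-based bp).
#' @param promoter_start,promoter_end promoter intervals (0-based
#'   half-open) containing the TSS.
#' @param bait_start,bait_end bait fragments, NA when the gene is not
#'   baited.
#' @param chrom chromosome label.
#' @return data.table of class \code{"ldhicGeneAnnotation"}.
#' @export
geneAnnotation <- function(gene_id, tss, promoter_start, promoter_end,
                           bait_start = NA_integer_,
                           bait_end = NA_integer_, chrom = "chrS") {
  ann <- data.table(gene_id = as.character(gene_id),
                    tss = as.integer(tss),
                    promoter_start = as.integer(promoter_start),
                    promoter_end = as.integer(promoter_end),
                    bait_start = as.integer(bait_start),
                    bait_end = as.integer(bait_end))
  if (anyDuplicated(ann$gene_id)) stop("gene_id must be unique")
  # promoter [s, e) must contain the 1-based TSS, i.e. s < tss <= e
  if (any(!(ann$promoter_start < ann$tss & ann$tss <= ann$promoter_end)))
    stop("promoter must contain the TSS")
  data.table::setattr(ann, "chrom", chrom)
  data.table::setattr(ann, "class",
                      c("ldhicGeneAnnotation", class(ann)))
  ann[]
}

#' Per-interaction feature flags for enrichment contrasts
#'
#' Computes the four binary vectors compared in the eQTL analyses:
#' \code{has_eqtl} (some eQTL SNP lies in the PIR and its target gene's
#' bait fragment equals the interaction's bait), \code{significant},
#' \code{closest_gene_in_bait} (the gene whose promoter is nearest the PIR,
#' ties broken by smaller gene_id, is the bait gene), and \code{strong_ld}
#' (maximum cross-anchor r-squared > \code{ldThresh} in any population).
#'
#' @param interactions an [InteractionTrack-class] (pchic orientation:
#'   anchor 1 = bait, anchor 2 = PIR).
#' @param eqtls data.frame with \code{snp_pos} (1-based) and
#'   \code{gene_id}.
#' @param annotation a [geneAnnotation()].
#' @param pairs LD pair table; may contain several populations.
#' @param ldThresh strong-LD cutoff (default 0.8).
#' @return data.table of flags, one row per interaction.
#' @export
interactionFeatureVectors <- function(interactions, eqtls, annotation,
                                      pairs, ldThresh = 0.8) {
  eq <- as.data.table(eqtls)
  missing <- setdiff(eq$gene_id, annotation$gene_id)
  if (length(missing))
    stop("eQTL target genes absent from annotation: ",
         paste(unique(missing), collapse = ", "))
  n <- length(interactions)
  baitGene <- baitGeneOf(interactions, annotation)
  # has_eqtl: SNP in PIR and target's bait equals this bait
  eq <- merge(eq, annotation[, c("gene_id", "bait_start", "bait_end")],
              by = "gene_id")
  pir <- anchorTwo(interactions)
  hasEqtl <- logical(n)
  if (nrow(eq)) {
    sr <- IRanges(start = eq$snp_pos, end = eq$snp_pos)
    ov <- findOverlaps(sr, pir)
    k <- subjectHits(ov)
    baitS <- start(anchorOne(interactions))[k] - 1L
    baitE <- end(anchorOne(interactions))[k]
    match_ <- eq$bait_start[queryHits(ov)] == baitS &
              eq$bait_end[queryHits(ov)] == baitE
    hasEqtl[unique(k[which(match_)])] <- TRUE
  }
  # closest gene to the PIR (interval distance from promoter to PIR)
  promR <- IRanges(start = annotation$promoter_start + 1L,
                   end = annotation$promoter_end)
  ordAnn <- order(annotation$gene_id)
  closest <- vapply(seq_len(n), function(k) {
    d <- pmax(start(pir)[k] - end(promR), start(promR) - end(pir)[k], 0L)
    cand <- which(d == min(d))
    cand <- cand[order(annotation$gene_id[cand])][1]
    annotation$gene_id[cand]
  }, "")
  closestInBait <- !is.na(baitGene) & closest == baitGene
  # strong LD in any population
  pops <- unique(pairs$population)
  strongLd <- rep(FALSE, n)
  for (pop in pops) {
    ml <- interactionMaxLD(interactions,
                           pairs[pairs$population == pop, ])
    strongLd <- strongLd | ml$maxLd > ldThresh
  }
  data.table(has_eqtl = hasEqtl, significant = isSignificant(interactions),
             closest_gene_in_bait = closestInBait, strong_ld = strongLd,
             bait_gene = baitGene,
             distance = interactionDistances(interactions))
}

#' Quantile distance bins for interactions
#'
#' Bins interactions by the empirical quantiles of their distances up to
#' \code{maxDist} (records beyond are dropped with a message), so every
#' bin holds a near-equal share and contingency tables avoid zero cells.
#'
#' @param interactions an [InteractionTrack-class].
#' @param maxDist maximum distance retained (default 2 Mb).
#' @param nBins number of quantile bins.
#' @return List: \code{bin} (integer label per retained interaction, NA
#'   for dropped), \code{edges}, \code{nDropped}.
#' @export
quantileDistanceBins <- function(interactions, maxDist = 2e6, nBins = 4L) {
  d <- interactionDistances(interactions)
  keep <- d <= maxDist
  nDropped <- sum(!keep)
  if (nDropped) message(nDropped, " interactions beyond maxDist dropped")
  dk <- d[keep]
  if (length(dk) < nBins)
    stop("fewer interactions than requested bins")
  edges <- unique(quantile(dk, seq(0, 1, length.out = nBins + 1L),
                           names = FALSE))
  if (length(edges) < nBins + 1L)
    stop("tied distances collapse quantile bins; reduce nBins")
  bin <- rep(NA_integer_, length(d))
  bin[keep] <- pmax(pmin(findInterval(dk, edges, left.open = TRUE),
                         nBins), 1L)
  list(bin = bin, edges = edges, nDropped = nDropped)
}

# Wald 2x2 odds ratio with Haldane-Anscombe correction; identical to the
# single-binary-covariate logistic regression estimate (asserted in tests
# against an IRLS fit)
wald2x2 <- function(a, b, c_, d, conf = 0.95) {
  if (any(c(a, b, c_, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  lor <- log(a * d / (b * c_))
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  z <- qnorm(1 - (1 - conf) / 2)
  list(or = exp(lor), logOr = lor, ciLow = exp(lor - z * se),
       ciHigh = exp(lor + z * se), p = 2 * pnorm(-abs(lor / se)))
}

#' Stratified odds ratios over distance bins
#'
#' Per stratum, the 2x2 table of condition \code{x} against outcome
#' \code{y} gives the sample odds ratio ad/bc with Haldane-Anscombe 0.5
#' correction when a cell is empty, a Wald CI on the log odds ratio and a
#' Wald p-value. With a single binary covariate this coincides with the
#' logistic-regression estimate.
#'
#' @param y outcome flags (e.g. has_eqtl).
#' @param x condition flags (e.g. significant).
#' @param bins stratum labels; NA rows are dropped.
#' @param conf CI level.
#' @return data.table: stratum, a, b, c, d, or_estimate, log_or, ci_low,
#'   ci_high, p (NA with a reason when a stratum has a single x class).
#' @export
stratifiedOR <- function(y, x, bins, conf = 0.95) {
  keep <- !is.na(bins)
  y <- y[keep]; x <- x[keep]; bins <- bins[keep]
  out <- lapply(sort(unique(bins)), function(s) {
    ys <- y[bins == s]; xs <- x[bins == s]
    if (length(unique(xs)) < 2L)
      return(data.table(stratum = s, a = NA_integer_, b = NA_integer_,
                        c = NA_integer_, d = NA_integer_,
                        or_estimate = NA_real_, log_or = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                        note = "single x class"))
    a <- sum(xs & ys); b <- sum(xs & !ys)
    c_ <- sum(!xs & ys); d <- sum(!xs & !ys)
    w <- wald2x2(a, b, c_, d, conf)
    data.table(stratum = s, a = a, b = b, c = c_, d = d,
               or_estimate = w$or, log_or = w$logOr, ci_low = w$ciLow,
               ci_high = w$ciHigh, p = w$p, note = "")
  })
  data.table::rbindlist(out)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value conditional on the margins: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed the observed table's (within a small relative
#' tolerance). The sample odds ratio ad/bc is reported.
#'
#' @param a,b,c,d cell counts (row 1: a, b; row 2: c, d).
#' @return List: \code{or} (sample odds ratio), \code{p}.
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; n1 <- a + c; n2 <- b + d
  if (m1 == 0 || m2 == 0 || n1 == 0 || n2 == 0)
    stop("all margins must be positive")
  lo <- max(0L, n1 - m2); hi <- min(n1, m1)
  support <- lo:hi
  probs <- dhyper(support, m1, m2, n1)
  pObs <- dhyper(a, m1, m2, n1)
  p <- sum(probs[probs <= pObs * (1 + 1e-7)])
  or <- if (b == 0 || c == 0) Inf else a * d / (b * c)
  if (a == 0 || d == 0) or <- ifelse(b == 0 || c == 0, NaN, 0)
  list(or = or, p = min(p, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control; a thin, input-checked wrapper
#' around the standard adjustment, returning q-values in the original
#' order.
#'
#' @param pvals p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bhAdjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Map SNPs to genes by three strategies
#'
#' \describe{
#'   \item{closest}{the single gene whose promoter is nearest the SNP
#'     (interval distance, 0 when inside; ties broken by smaller
#'     gene_id).}
#'   \item{ld_block}{all genes whose promoter overlaps the LD block
#'     containing the SNP (empty when the SNP is in no block).}
#'   \item{pchic}{all bait genes of significant interactions whose PIR
#'     contains the SNP.}
#' }
#'
#' @param snps 1-based SNP positions.
#' @param strategy one of "closest", "ld_block", "pchic".
#' @param annotation a [geneAnnotation()].
#' @param blocks block table (required for "ld_block").
#' @param interactions an [InteractionTrack-class] (required for
#'   "pchic").
#' @return List of character vectors of gene ids, one per SNP.
#' @export
snpToGenes <- function(snps, strategy = c("closest", "ld_block", "pchic"),
                       annotation, blocks = NULL, interactions = NULL) {
  strategy <- match.arg(strategy)
  if (!nrow(annotation)) stop("empty annotation")
  promR <- IRanges(start = annotation$promoter_start + 1L,
                   end = annotation$promoter_end)
  if (strategy == "closest") {
    lapply(snps, function(p) {
      d <- pmax(start(promR) - p, p - end(promR), 0L)
      cand <- which(d == min(d))
      sort(annotation$gene_id[cand])[1]
    })
  } else if (strategy == "ld_block") {
    if (is.null(blocks)) stop("ld_block strategy requires blocks")
    lapply(snps, function(p) {
      hit <- which(blocks$start <= p & p <= blocks$end)
      if (!length(hit)) return(character())
      br <- IRanges(start = blocks$start[hit[1]], end = blocks$end[hit[1]])
      ov <- findOverlaps(promR, br)
      sort(unique(annotation$gene_id[queryHits(ov)]))
    })
  } else {
    if (is.null(interactions)) stop("pchic strategy requires interactions")
    sig <- subsetInteractions(interactions, isSignificant(interactions))
    bg <- baitGeneOf(sig, annotation)
    pir <- anchorTwo(sig)
    lapply(snps, function(p) {
      v <- bg[start(pir) <= p & p <= end(pir)]
      sort(unique(v[!is.na(v)]))
    })
  }
}

#' GO-term enrichment compared across SNP-to-gene strategies
#'
#' For the \code{pchic} strategy the unit is the significant interaction:
#' the 2x2 table crosses "PIR contains a GWAS SNP of the phenotype" with
#' "bait gene carries the term". For \code{closest} and \code{ld_block}
#' the unit is the gene: "assigned to the phenotype by the strategy"
#' against "carries the term". Each table gets a Fisher exact p; BH
#' adjustment is applied within phenotype x strategy across terms, and
#' significant-term counts are reported at each FDR level.
#'
#' @param gwas data.frame with \code{phenotype} and \code{pos}.
#' @param annotation a [geneAnnotation()].
#' @param go long data.frame with \code{gene_id}, \code{term}.
#' @param blocks block table (for ld_block).
#' @param interactions an [InteractionTrack-class] (for pchic).
#' @param strategies subset of the three strategies.
#' @param fdrLevels FDR cutoffs to count significant terms at.
#' @return List: \code{results} (long table with a, b, c, d, or, p, q) and
#'   \code{counts} (significant terms per phenotype x strategy x level).
#' @export
goEnrichmentCompare <- function(gwas, annotation, go, blocks = NULL,
                                interactions = NULL,
                                strategies = c("pchic", "closest",
                                               "ld_block"),
                                fdrLevels = c(0.01, 0.05, 0.10)) {
  gwas <- as.data.table(gwas)
  go <- as.data.table(go)
  if (!nrow(go)) stop("empty GO annotation")
  if (!nrow(gwas)) stop("at least one phenotype required")
  terms <- sort(unique(go$term))
  goSets <- split(go$gene_id, go$term)
  res <- list()
  for (ph in unique(gwas$phenotype)) {
    snps <- gwas$pos[gwas$phenotype == ph]
    for (st in strategies) {
      if (st == "pchic") {
        if (is.null(interactions)) stop("pchic strategy requires interactions")
        sig <- subsetInteractions(interactions,
                                  isSignificant(interactions))
        bg <- baitGeneOf(sig, annotation)
        ok <- !is.na(bg)
        sig <- subsetInteractions(sig, ok); bg <- bg[ok]
        pir <- anchorTwo(sig)
        sr <- IRanges(start = snps, end = snps)
        hasSnp <- rep(FALSE, length(sig))
        hasSnp[unique(subjectHits(findOverlaps(sr, pir)))] <- TRUE
        units <- data.table(gene = bg, x = hasSnp)
      } else {
        assigned <- unique(unlist(snpToGenes(snps, st, annotation,
                                             blocks = blocks,
                                             interactions = interactions)))
        units <- data.table(gene = annotation$gene_id,
                            x = annotation$gene_id %in% assigned)
      }
      if (!any(units$x)) {
        res[[length(res) + 1L]] <- data.table(
          phenotype = ph, strategy = st, term = NA_character_,
          a = NA_integer_, b = NA_integer_, c = NA_integer_,
          d = NA_integer_, or_estimate = NA_real_, p = NA_real_,
          q = NA_real_, note = "no mapped genes")
        next
      }
      rows <- lapply(terms, function(tm) {
        hasTerm <- units$gene %in% goSets[[tm]]
        a <- sum(units$x & hasTerm); b <- sum(units$x & !hasTerm)
        c_ <- sum(!units$x & hasTerm); d <- sum(!units$x & !hasTerm)
        if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0)
          return(data.table(phenotype = ph, strategy = st, term = tm,
                            a = a, b = b, c = c_, d = d,
                            or_estimate = NA_real_, p = NA_real_,
                            q = NA_real_, note = "degenerate margin"))
        f <- fisherExact2x2(a, b, c_, d)
        data.table(phenotype = ph, strategy = st, term = tm, a = a, b = b,
                   c = c_, d = d, or_estimate = f$or, p = f$p,
                   q = NA_real_, note = "")
      })
      tab <- data.table::rbindlist(rows)
      ok <- !is.na(tab$p)
      if (any(ok)) tab$q[ok] <- bhAdjust(tab$p[ok])
      res[[length(res) + 1L]] <- tab
    }
  }
  results <- data.table::rbindlist(res)
  counts <- data.table::rbindlist(lapply(fdrLevels, function(fl)
    results[!is.na(q), .(fdr = fl, n_significant = sum(q < fl)),
            by = .(phenotype, strategy)]))
  list(results = results, counts = counts)
}
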