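#' Run the full synthetic LD / chromatin comparison pipeline
#'
#' Executes every stage in dependency order on one synthetic chromosome:
#' simulate the haplotype panel and contact map, scan pairwise LD and call
#' blocks, normalize the matrix and compute observed/expected, build the
#' bin-pair track and concordance curves, simulate interaction calls with
#' distance-matched shuffled negatives and compute the interaction-LD log
#' ratio and same-block fraction, run the boundary permutation test, and
#' compute eQTL and GO enrichment on simulated regulatory fixtures. All
#' result tables are written as TSV to \code{outdir} together with a JSON
#' run manifest recording the seed and parameters; two runs with the same
#' configuration produce identical tables.
#'
#' @param config a [simulationConfig()].
#' @param outdir output directory (created if needed).
#' @param nPos,nNeg interaction calls to simulate.
#' @param nBoot bootstrap resamples for the log-ratio CI.
#' @param nPerm permutations for the boundary test.
#' @param orProximal,orDistal,baseRate planted regulatory parameters.
#' @param blockGridStep D' grid step for block calling.
#' @return Invisibly, a named list of the result tables.
#' @export
runPipeline <- function(config = simulationConfig(), outdir,
                        nPos = 40L, nNeg = 80L, nBoot = 400L,
                        nPerm = 200L, orProximal = 20, orDistal = 4,
                        baseRate = 0.05, blockGridStep = 0.005) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  hap <- simulateHaplotypes(config)
  cmSim <- simulateContactMap(config)
  pairs <- pairwiseLDScan(hap$panel, mafMin = config$mafFloor)
  blocks <- callLDBlocks(hap$panel, mafMin = config$mafFloor,
                         gridStep = blockGridStep)
  cm <- computeExpected(vcNormalize(cmSim$matrix))
  track <- buildBinPairTrack(pairs, cm,
                             positions = snpPositions(hap$panel))
  conc <- concordanceByWindow(track)
  dec <- decayProfile(pairs, cm)
  calls <- simulateInteractionCalls(cm, cmSim$truth, nPos = nPos,
                                    nNeg = nNeg, seed = seed)
  positives <- subsetInteractions(calls, isSignificant(calls))
  shuffled <- shuffleSameChrom(positives, config$chromLength, seed = seed)
  ild <- interactionLDLogRatio(positives, shuffled, pairs,
                               nBoot = nBoot, seed = seed)
  sbf <- sameBlockFraction(positives, blocks)
  bt <- boundaryPermutationTest(
    boundarySet(do.call(rbind, lapply(config$domainIntervals, function(iv)
      data.frame(start = iv[1], end = iv[2])))),
    blocks, config$chromLength, nPerm = nPerm, seed = seed)
  ann <- annotationFromBaits(calls, config$chromLength, seed = seed)
  reg <- simulateRegulatoryFixtures(calls, ann, orProximal = orProximal,
                                    orDistal = orDistal,
                                    baseRate = baseRate, seed = seed,
                                    chromLength = config$chromLength)
  fv <- interactionFeatureVectors(calls, reg$eqtls, ann, pairs)
  distBin <- ifelse(fv$distance < 2e5, "proximal", "distal")
  eq <- stratifiedOR(fv$has_eqtl, fv$significant, distBin)
  goCmp <- goEnrichmentCompare(reg$gwas, ann, reg$go, blocks = blocks,
                               interactions = calls)
  tables <- list(
    ld_pairs = pairs,
    ld_blocks = blocks,
    concordance = conc,
    decay_profile = dec$profile,
    interaction_ld = data.table(
      mean_pos = ild$meanPos, mean_neg = ild$meanNeg,
      log_ratio = ild$logRatio, ci_low = ild$ciLow, ci_high = ild$ciHigh,
      same_block_fraction = sbf),
    boundary_test = data.table(
      observed_median = bt$observedMedian,
      null_median_q05 = quantile(bt$nullMedians, 0.05, names = FALSE),
      null_median_q50 = quantile(bt$nullMedians, 0.50, names = FALSE),
      null_median_q95 = quantile(bt$nullMedians, 0.95, names = FALSE),
      p = bt$p),
    eqtl_enrichment = eq,
    go_enrichment = goCmp$results)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) signif(v, 6))
    utils::write.table(df, file.path(outdir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = "ldhic",
    version = as.character(utils::packageVersion("ldhic")),
    seed = seed,
    coupling = config$coupling,
    parameters = config[setdiff(names(config),
                                c("domainIntervals", "loopAnchors"))],
    n_domains = length(config$domainIntervals),
    n_loops = length(config$loopAnchors),
    tables = paste0(names(tables), ".tsv"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(tables)
}
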