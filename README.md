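# ldhic

Tools for comparing the two pairwise architectures of a chromosome:
linkage disequilibrium (LD), the genetic association between alleles at
pairs of loci, and chromatin contact frequency, the physical interaction
between pairs of genomic regions. Both are high at short genomic distance
and both form block patterns (haplotype blocks; contact domains), which
invites the question of whether the blocks coincide — and with it the
practical question of whether LD is a usable proxy for which genes a
noncoding variant physically contacts. `ldhic` implements the full
analysis stack for that comparison and a synthetic-data module with
planted, machine-readable truth so every estimator is testable end to end
without external downloads.

Who it is for: statistical geneticists and regulatory genomicists who
want the comparison machinery (or any piece of it — LD block calling,
contact-map normalization, distance-matched interaction nulls, enrichment
contrasts) as tested, reusable R functions.

## What is implemented

* **LD core** — pairwise r² and D′ from phased haplotype panels
  (`pairwiseLDScan`, r² = D²/(p_A(1−p_A)p_B(1−p_B)), D′ = |D|/D_max), EM
  haplotype frequencies for unphased two-locus tables, likelihood-grid
  confidence intervals for |D′|, and confidence-interval (Gabriel-style)
  haplotype-block calling (`callLDBlocks`) with the strong-LD /
  strong-recombination classification and a greedy non-overlap rule.
* **Hi-C core** — sparse binned contact matrices, vanilla-coverage
  normalization (`vcNormalize`), expected-by-distance and
  observed/expected transforms with exact per-diagonal unit-mean
  identities.
* **Concordance** — bin-pair tracks joining the 75th-percentile LD summary
  with O/E contacts, multi-scale concordance of strong-LD and
  frequent-contact masks across window sizes 5–1280 kb
  (`concordanceByWindow`), with both product-of-marginals and
  distance-stratified no-association references; distance-decay profiles
  with Spearman correlations.
* **Interaction-level LD** — per-interaction maximum cross-anchor r²,
  the log ratio of mean interaction LD for significant vs distance-matched
  non-significant interactions with bootstrap (BCa) intervals,
  exact distance-preserving shuffles and quantile distance matching, and
  same-LD-block fractions.
* **Boundary statistics** — distances between contact-domain boundaries
  and nearest LD-block boundaries, with a length-preserving permutation
  test (`boundaryPermutationTest`).
* **Enrichment** — eQTL enrichment odds ratios per distance stratum
  (Haldane-corrected 2×2 Wald, equivalent to single-covariate logistic
  regression), Fisher exact tests, BH adjustment, and GO-term enrichment
  compared across three SNP-to-gene strategies (closest gene, same LD
  block, promoter-capture interactions).
* **Synthetic data** — founder-mosaic haplotype panels with planted
  recombination hotspots, Poisson contact maps with planted domains and
  loops, CHiCAGO-like interaction calls with the score-5 significance
  convention, and eQTL/GWAS/GO fixtures with planted odds ratios, under
  three couplings (`independent`, `boundary_coincident`, `anchor_ld`).
* **IO / pipeline** — phased VCF + population panel, BED/BEDPE (0-based
  half-open), triplet-text contact matrices, and `runPipeline()`, which
  runs every stage on one synthetic chromosome and writes eight TSV result
  tables plus a JSON manifest, reproducibly per seed.

## Worked example

A coupled scenario in which recombination hotspots sit at contact-domain
boundaries and LD is strong only inside domains:

```r
library(ldhic)

cfg <- simulationConfig(seed = 1, coupling = "boundary_coincident")
hap <- simulateHaplotypes(cfg)
hap$panel
#> HaplotypePanel: 200 haplotypes x 602 SNPs on chrS
#>   positions: 14342 - 2554385 bp; populations: POP1

pairs  <- pairwiseLDScan(hap$panel)      # 28616 stored pairs (r2 >= 0.01)
blocks <- callLDBlocks(hap$panel, gridStep = 0.005)
nrow(blocks); median(blocks$end - blocks$start)
#> [1] 44
#> [1] 4758

cm    <- computeExpected(vcNormalize(simulateContactMap(cfg)$matrix))
track <- buildBinPairTrack(pairs, cm, positions = snpPositions(hap$panel))
concordanceByWindow(track, expected = "stratified")[2:5]
#>    window_size n_pairs   observed   expected
#> 1:       10000     133 0.19548872 0.05596699
#> 2:       20000     402 0.14925373 0.04263507
#> 3:       40000     932 0.09334764 0.02732756
#> 4:       80000    1993 0.05469142 0.01554223
```

Strong LD and frequent contacts co-occur 3–4× more often than the
distance-matched no-association reference — the planted coupling is
recovered. The boundary permutation test agrees that block boundaries sit
closer to domain boundaries than random placement would put them:

```r
domB <- boundarySet(do.call(rbind, lapply(cfg$domainIntervals,
        function(iv) data.frame(start = iv[1], end = iv[2]))))
bt <- boundaryPermutationTest(domB, blocks, cfg$chromLength,
                              nPerm = 499, alternative = "shorter", seed = 1)
c(observed = bt$observedMedian, null_median = median(bt$nullMedians), p = bt$p)
#>    observed null_median           p
#>    3882.500   14999.500       0.002
```

The observed median distance from a domain boundary to the nearest block
boundary (3.9 kb) is far below the permutation null's typical 15 kb.
Under the `independent` coupling the same pipeline returns concordance
excesses near zero and interaction-LD log ratios whose intervals cover 0,
which is the calibration the test suite asserts over 100 seeds.

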