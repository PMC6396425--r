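---
title: "Methods: comparing linkage disequilibrium and chromatin interaction maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing linkage disequilibrium and chromatin interaction maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldhic)
```

# The question the package addresses

Linkage disequilibrium (LD) and chromatin contact frequency are both
pairwise measures between genomic loci, and both decay with genomic
distance while showing block-like structure along the chromosome: haplotype
blocks bounded by recombination hotspots on the genetic side, contact
domains bounded by insulator elements on the physical side. Whether these
two architectures coincide matters for interpreting noncoding variants: if
LD blocks tracked chromatin domains, a GWAS SNP's LD partners would be a
good proxy for the genes it physically contacts. `ldhic` implements the
statistical machinery needed to ask this question quantitatively — LD
computation and block calling, contact-map normalization, multi-scale
concordance, interaction-level LD contrasts against distance-matched
nulls, boundary permutation tests, and eQTL/GO enrichment comparisons
between SNP-to-gene mapping strategies — together with a synthetic-data
module that generates the inputs with planted, machine-readable truth so
that every estimator can be validated end to end.

# Pairwise LD and haplotype blocks

For two biallelic loci with haplotype frequency $p_{AB}$ and allele
frequencies $p_A$, $p_B$, the package computes
$D = p_{AB} - p_A p_B$, $r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$, and
$D' = |D| / D_{\max}$, with $D_{\max}$ the frequency-imposed bound given
the sign of $D$. `pairwiseLDScan()` evaluates all pairs within 2 Mb among
SNPs with minor-allele frequency at least 5% and stores pairs with
$r^2 \ge 0.01$; sub-floor pairs are treated as zero downstream. These
defaults mirror the standard large-scale scan settings for phased
reference panels and are exposed as arguments.

Phased input is the primary path; unphased two-locus genotype tables route
through `emHaplotypeFreqs()`, a standard EM in which only double
heterozygotes are phase-ambiguous. The symmetric table of all double
heterozygotes is a fixed point of the EM at (0.25, 0.25, 0.25, 0.25); this
degenerate case is documented rather than special-cased, since the
likelihood there is flat in $D$.

Haplotype blocks use the confidence-interval (Gabriel-style) definition.
`dprimeCI()` profiles the multinomial likelihood over a grid on $|D'|$
(step 0.001 single-pair, 0.002 for the batched classification; the
thresholds 0.70/0.90/0.98 lie on both grids) with allele frequencies fixed
at their MLEs and the sign of $D$ fixed at its point estimate, and takes
one-sided 5%/95% bounds. Pairs are "strong LD" when the CI lies above
(0.70, 0.98), "strong recombination" when the upper bound is below 0.90,
otherwise uninformative. A candidate block requires a strong-LD outermost
pair and at least 95% strong among informative inner pairs; candidates are
accepted greedily by bp span (ties: leftmost first) without overlap, with
a 2-Mb span cap and no small-block span caps. Monomorphic-by-MAF SNPs are
removed before classification rather than counted as uninformative. Exact
agreement with any particular external implementation's internals is not
claimed; correctness is asserted against the definitional formulas and
brute-force oracles.

# Contact matrices

`vcNormalize()` implements vanilla-coverage normalization: each count is
divided by the product of its two bins' symmetric coverage marginals and
rescaled so total mass is conserved. Zero-coverage bins are excluded
rather than smoothed, which keeps every downstream mean well defined.
`expectedByDistance()` averages normalized counts per diagonal with
structural zeros between included bins counted (a nonzero-only mode
exists), and `observedOverExpected()` divides by that profile, so the mean
O/E over each diagonal is exactly 1 by construction — an identity the
tests assert.

A practical subtlety documented here because it shaped the synthetic
study conditions: marginal-based balancing partially absorbs genuine block
structure. When boosted (domain) bins contribute a large share of their own
coverage — which happens when contact decay is steep and domains are
compact — dividing by the inflated marginals cancels much of the boost.
The coupled simulation scenario therefore uses a slower decay exponent
(0.7, within the range reported for within-domain contact decay) and a
higher depth so the planted domain contrast survives normalization.

# Multi-scale concordance

`buildBinPairTrack()` aggregates SNP-pair $r^2$ to bin pairs at the
contact-map resolution, summarizing each bin pair by the 75th percentile
(linear interpolation) over spanning SNP pairs, with dropped sub-floor
pairs counted back in as zeros when SNP positions are supplied. The
concordance unit is deliberately the bin *pair*: contact values are
intrinsically pairwise, so "a bin's LD value" is interpreted as the LD
summary of the bin pair being compared with its O/E entry.

`concordanceByWindow()` partitions the chromosome into non-overlapping
windows of each size (5 kb to 1280 kb by doubling), collects bin pairs
with both bins in one window, marks strong LD (summary > 0.8) and frequent
contact (above the 75th percentile of the collected contact values,
computed once per window-size analysis), and reports the observed
co-occurrence fraction against a no-association reference. Two references
are provided: the plain product of marginals (default), and a
distance-stratified product equivalent to averaging over random
reassignments of contact values among bin pairs at the same separation.
The stratified form is the calibrated null: because both measures vary
with distance, the plain product is confounded by the shared distance
dependence even when the two maps are generated independently — which is
itself the methodological point the concordance analysis is designed to
expose. The calibration tests use the stratified reference for this
reason.

One structural note: with 5-kb bins, a 5-kb window cannot contain a pair
of distinct bins, so the smallest window size reports no data and the
multi-scale curve is informative from 10 kb upward. Same-bin (diagonal)
pairs are excluded by design since sub-resolution proximity is not
comparable.

# Interaction-level LD

For each interaction, `interactionMaxLD()` takes the maximum stored
$r^2$ over cross-anchor SNP pairs (absent pairs count 0; records with an
empty anchor contribute 0 by default and can be dropped via a flag).
`interactionLDLogRatio()` compares significant interactions with
distance-matched non-significant ones via the natural log of the ratio of
mean max-LD, the scale on which "no elevation" is 0. Confidence intervals
come from a nonparametric bootstrap over interactions; the default
interval is BCa (bias-corrected, with two-sample jackknife acceleration),
which we found necessary for near-nominal coverage given the zero-inflated,
skewed distribution of per-interaction max LD; a plain percentile mode is
available.

Two distance-matching constructions are provided, mirroring the two data
modalities. `shuffleSameChrom()` jointly shifts each record to a uniform
position on the same chromosome, preserving anchor lengths and separation
exactly (hence exactly distance-matched), redrawing placements that
overlap any positive anchor. `quantileDistanceMatch()` samples
non-significant candidates within positive-distance quantile bins
(default 20 bins).

# Boundary statistics

Domain and block edges are reduced to point coordinates.
`boundaryPermutationTest()` compares the observed median distance from
each domain boundary to its nearest block boundary against the medians
after placing the blocks (lengths and count preserved) uniformly without
overlap; a gap-preserving circular-rotation mode is available since the
choice of permutation scheme is a genuinely open design point. P-values
use the add-one rule, $(1 + \#\{\text{as extreme}\})/(n_{perm}+1)$, so
they are never 0, and the direction ("longer" = boundary avoidance,
the default, per the phenomenon of long blocks spanning domain
boundaries; "shorter" = coincidence) is explicit.

# Enrichment analyses

The eQTL contrast is built from per-interaction flags: an interaction
"has an eQTL" when some eQTL SNP falls in its promoter-interacting region
(PIR) and the eQTL's target gene is the bait gene (the gene whose bait
fragment equals the interaction's bait). Odds ratios per distance stratum
use the 2x2 sample OR with Haldane–Anscombe 0.5 correction on empty cells
and Wald intervals; with a single binary covariate this coincides with the
logistic-regression estimate, an equivalence the test suite asserts
against an IRLS fit written independently in the tests. Interactions are
quantile-binned by distance (up to 2 Mb) so no stratum has empty margins.

GO enrichment crosses "interaction's PIR holds a GWAS SNP of the
phenotype" with "bait gene carries the term" in a Fisher exact test per
(phenotype, term), implemented by hypergeometric enumeration and verified
against exhaustive enumeration of all tables with margins up to 30. For
the closest-gene and same-LD-block strategies the 2x2 unit is the gene
(assigned to the phenotype by the strategy x carries the term); the
gene-level reading is a documented interpretation choice. BH adjustment is
applied within phenotype x strategy across terms (a global-family option
exists), and closest-gene ties break lexicographically by gene identifier
since any external tool's tie behavior is unspecified.

# The synthetic-data generators

`simulateHaplotypes()` uses a founder-mosaic model: founder haplotypes are
i.i.d. Bernoulli(0.5) per site, and each haplotype re-draws its founder
between consecutive SNPs with a per-interval switch probability —
background 0.10, or 0.9 where a recombination hotspot lies in the
interval. With the default two founders every founder-conserved segment is
in perfect internal LD and hotspots break LD locally, giving direct,
local control of planted block boundaries at O(haplotypes x SNPs) cost;
this is a deliberate trade against coalescent realism, because the tests
need planted boundaries, not genealogies. More founders dilute
within-segment LD (founder columns are nearly independent), so two is the
default and the parameter is exposed. The MAF floor (0.05) is applied
after simulation, mirroring the scan's filter; with two founders roughly
half the generated sites are monomorphic and drop out, which the default
SNP count (1200 on a 2.56-Mb chromosome, giving ~600 segregating SNPs and
an LD half-length of roughly 10 kb) anticipates. Sample sizes default to
200 haplotypes, on the order of a reference-panel population.

`simulateContactMap()` draws Poisson counts with rate proportional to
$b_i b_j (d+1)^{-\alpha}$ times a domain boost (3) for same-domain pairs
and a loop boost (5) for planted anchor pairs, with lognormal per-bin
visibility biases (sigma 0.3) and the total calibrated to the expected
depth (1e6). Poisson (no overdispersion) suffices because interaction
calling is out of scope; calls are planted. `simulateInteractionCalls()`
anchors positives at planted loops plus top-O/E pairs (each bin used by at
most one positive, keeping records statistically distinct), draws
positive scores as 5 + Exp(1) and negative scores uniform below 5 — the
conventional score-5 significance threshold with exact boundary semantics
(5.0 is significant; 4.999 is not) — on 2-bin (10-kb) anchors, with
midpoint-to-midpoint distances.

`simulateRegulatoryFixtures()` emits an eQTL per interaction with
probability $b\,\mathrm{OR}/(1-b+b\,\mathrm{OR})$ when significant and $b$
otherwise, with OR 20 below 200 kb and 4 beyond, so the marginal 2x2 odds
ratio in each stratum equals the planted value; a planted GO term covers
the bait genes of one phenotype's SNP-bearing interactions.

Three couplings define the study scenarios. *independent* draws hotspots
uniformly, independent of domains and loops; LD and contacts then share
only genomic distance, which is exactly what the stratified concordance
reference conditions away. *boundary_coincident* places hotspots at
domain boundaries and switches founders at the hotspot rate everywhere
outside a domain, planting strong LD inside domains only; the preset uses
64-kb domains covering ~25% of the chromosome (so the top contact quartile
can align with them), decay 0.7 and depth 2e6 (see the normalization note
above). *anchor_ld* forces one SNP into each loop anchor and copies the
anchor-1 alleles to the anchor-2 SNP, planting perfect cross-anchor LD on
positive interactions.

What the generators deliberately do not emulate: realistic demography or
genealogies, multi-chromosome genomes, trans contacts, overdispersed
contact noise, CHiCAGO's or Juicer's significance machinery, and GO's
hierarchical term structure. Passing tests therefore demonstrate that the
estimators recover planted truth under these stylized conditions, not that
the biological conclusions transfer to any particular real data set.

# Problem sizes and numerical choices in the test suite

The validation suite runs the concordance calibration on 100 seeded
chromosomes per coupling (2.56 Mb, 512 bins), the interaction-LD
calibration on 100 seeds per coupling (5.12 Mb, 2400 SNPs, 60 positives
with 4 shuffle replicates, 600 bootstrap resamples), block recovery on 50
panels of 2000 haplotypes, boundary-test calibration on 400 null data sets
with 199 permutations each, and enrichment recovery on 100 runs of 5000
interactions; these sizes were chosen as the smallest at which the
planted effects and calibration targets are comfortably resolved.
Degenerate inputs are contracts, not surprises: all-zero matrices,
monomorphic loci, empty candidate bins, tied distances collapsing
quantile edges, and phenotypes mapping to no genes all raise informative
errors, and the add-one permutation p-value keeps p strictly positive.

# Limitations

Single-chromosome scope; VC (not matrix-balancing) normalization only;
the bin-pair reading of per-bin LD; planted rather than model-based
interaction significance; and bootstrap rather than exact inference for
the log-ratio. Each is either a documented design decision above or a
deliberate non-goal.
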