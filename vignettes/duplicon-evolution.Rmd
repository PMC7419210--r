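---
title: "Methods: permutation enrichment and molecular evolution of core-duplicon SDs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation enrichment and molecular evolution of core-duplicon SDs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupliconevo)
```

This vignette documents the statistical models behind `dupliconevo`, the
assumptions they make, the tunable parameters that matter, and the design
choices taken where the methodology was genuinely open. The package is a
set of R functions (plus `run_pipeline()` for seeded end-to-end runs);
the exported functions and this vignette are its interface — there is no
separate shell tool.

## The scientific setting

Core duplicons are short, transcriptionally active duplicated elements
found at the centre of interspersed segmental duplication (SD) blocks in
primate genomes. Studying one involves three recurring quantitative
questions, each with its own module here:

1. Are the genomic neighbourhoods involved in duplication — the *donor*
   segments that were co-duplicated, the unique *acceptor* sequence
   flanking each integration, and the *pre-integration* loci in outgroup
   genomes — biased in sequence composition (GC, SINE, LINE)?
2. What happens at the base-pair scale of each integration: which repeats
   sit at the breakpoints, and how much sequence was lost at the
   pre-integration site?
3. How do the gene paralogs carried by the duplicon evolve: is there an
   excess of amino-acid replacement substitutions, how do the copies
   group phylogenetically, and when did they duplicate?

## Permutation enrichment

For a region set of *n* intervals and a feature *f* ∈ {GC, SINE, LINE}
the observed value is compared with a null of `n_permutations` random
placement sets. Each placement keeps every interval's length and draws
its start uniformly over all genome positions where the interval fits
entirely inside one *allowed* segment — the genome minus an exclusion
mask of SDs, centromeres, telomeres and assembly gaps. Placements are
mutually independent, may overlap one another, and are free to change
chromosome: the exclusion set is the only constraint the null encodes, so
this is the simplest null consistent with it. Statistics:

* **Enrichment coefficient** E = observed / mean(null).
* **GC**: per-region values are overlap-weighted window-GC fractions, the
  aggregate is their mean (not pooled-base GC — this keeps the aggregate
  consistent with the per-region sample that enters the KS test). The
  p-value is a two-sample Kolmogorov–Smirnov test of the observed
  per-region values against per-region values pooled across all
  permutations (capped at 10⁵ by seeded subsampling; the choice of null
  sample for the KS test was open, and pooling across placements is the
  least wasteful option). The asymptotic Kolmogorov distribution is
  evaluated at √(n₁n₂/(n₁+n₂))·D. The Z-transform p is also reported for
  GC so both conventions are available.
* **SINE/LINE**: per-region values are distinct-element overlap counts
  (≥ 1 bp, each element counted once per region even when it spans two);
  the aggregate is the total of the per-region counts. For the
  nonredundant (merged) region sets these analyses use, this equals the
  set-level distinct count; for artificially overlapping sets it is the
  linear statistic whose null expectation is placement-invariant, which
  is why the planted-enrichment recovery below is unbiased. The p-value
  is the upper tail of the standard normal at
  z = (obs − μ₀)/σ₀ (enrichment direction; a depletion mode exists but
  is off by default).
* **Correction and error**: Bonferroni over the family actually run
  (3 region classes × 3 features = 9), and SE = √(p(1−p)/n) treating the
  raw p as a binomial proportion over the *n* regions tested. A test is
  starred when corrected p + SE ≤ 0.05.

One printed inconsistency is worth recording: the published ± values for
the 27 acceptor regions are consistent with a larger *n* (≈ 55) in the SE
formula than the region count printed beside them, and neither the
redundant count (37) nor the nonredundant one (27) reproduces them.
`p_value_se(p, n_regions)` therefore takes *n* explicitly; the donor
(n = 63) and pre-integration (n = 13) columns verify exactly.

**Problem sizes.** The full-scale analysis uses 10,000 permutations; the
packaged tests recover a planted E at 2,000 permutations (the Monte-Carlo
error of the null mean is then far below the placement noise of the
donors themselves) and calibrate the type-I error over 200 simulated
null datasets at 150 permutations each, sizes chosen so the whole suite
runs in minutes on one CPU.

## Junctions, deletions and clone screens

`classify_boundary()` scans a closed ±50 bp window around each
duplication-transition breakpoint; an element merely touching the window
counts ("precisely at the breakpoint" argues for inclusivity; the window
is configurable), and a SINE hit dominates other classes. Deletion at a
pre-integration site is the anchor span on the outgroup assembly,
reported in kbp rounded to 0.1; zero is a legal value (precise
integration). The deletion summary's median treats the no-loss locus as
0 kbp — over the 13-locus packaged table this reproduces the printed
median (5.8 kbp) exactly, and the 12-locus alternative (5.85 kbp) is
reported alongside. Two further notes on that table: (i) for three rows
the printed anchor span does not reproduce the printed deletion size
(residuals 0.5–7.8 kbp); the fixture ships the printed deletion values
and the span rule is validated on the rows where it holds. (ii) The mean
of the Repeats(%) column recomputed from the table (72.2 over the 12 rows
reporting composition) differs from the printed average (67.56); the
package reports what it computes.

Clone-screen copy number is clones/coverage; with a coverage range the
estimate is a range and only bounds (e.g. "> 15 copies" from 110 clones
at 6–7×) are treated as reproducible, because the rounding behind the
printed integer copy numbers is unstated.

## Modified Nei–Gojobori selection tests

Each codon position distributes one potential site across its three
single-base changes, the transition weighted R/(R+1) and each
transversion ½·1/(R+1); R = 0.5 recovers the original unweighted method
and is the default, since the ratio the original analysis used is not
stated (every output records the R used). Changes into stop codons are
removed and the remaining weights renormalized per position, so
n_nonsyn + n_syn = 3 holds for every sense codon and N + S = 3·(codons)
for every sequence. Differences use pathway averaging: multi-difference
codons average the synonymous/nonsynonymous step counts over all
orderings of the single-base steps, excluding any pathway through a stop
(unweighted averaging — the classic convention; codons whose every
pathway is blocked are skipped and flagged). Proportions pN = Nd/N,
pS = Sd/S are corrected either as d = p or by Jukes–Cantor
d = −¾ ln(1 − 4p/3) (default, the common convention for this method
family), with matching delta-method variances; pS ≥ ¾ flags the pair
saturated. The test statistic is D = dN − dS with Z = D/σ,
σ = √(var dN + var dS) — the analytic large-sample σ, since the original
Z = D/σ is stated without defining σ and this is the standard choice; a
codon-bootstrap σ is deliberately not provided to keep one well-tested
path. The default direction is one-tailed for positive selection
(dN > dS), matching the hypothesis the test exists for; a purifying
direction is available.

**Group scans and pseudo-replication.** `group_selection_scan()` runs all
within-group pairwise comparisons per exon and reports both the mean of
the pairwise statistics and a pooled test on summed counts. Pairs within
a group share branches: in a group of *m* sequences each lineage enters
m − 1 of the m(m−1)/2 pairs, so the naive binomial variance of the
pooled counts is too small by a factor of about m − 1 (exact for a star
genealogy with equal branch lengths). The pooled test therefore deflates
the effective site totals by m − 1 before the Z-test. How the original
analysis pooled its pairwise comparisons is not specified; both
summaries are emitted so either convention can be inspected. With this
correction the simulated null rejection rate is near nominal at the
scales the tests use (group of 4, 300 codons, pairwise divergence
≈ 0.2 substitutions/codon); at materially lower synonymous counts the
asymptotic test becomes anticonservative, a known property of analytic
Z-tests on small counts.

Exon-resolved scans take an explicit codon partition and an exclusion
list defaulting to the C-terminal repeat-array exon (`"exon8"`), whose
global alignment is unreliable in this gene family; excluded exons are
absent from the output rather than present-but-flagged.

## Distance phylogenetics and timing

K2P distances use the closed form K = −½ ln((1−2P−Q)√(1−2Q)) on
pairwise-deleted sites with the usual delta-method standard error;
non-positive logarithm arguments flag the pair saturated rather than
erroring. Neighbor-joining follows the Saitou–Nei Q-criterion with
standard branch-length formulas; ties in Q are broken deterministically
by the lexicographically smallest pair of cluster representative labels,
and negative branch lengths are clamped to zero with a warning and a
count attribute (standard practice). NJ applied to an additive matrix
reconstructs the generating tree exactly, which the tests exploit as an
oracle. Bootstrap supports resample alignment columns with replacement,
rebuild K2P+NJ per replicate, and attach to each internal bipartition of
the full-data tree its replicate frequency (replicate trees are not
consensus-merged; saturated replicates are dropped and counted).
Tajima's relative rate test counts sites where exactly one ingroup
differs from the outgroup and compares m₁, m₂ by χ² on 1 df; m₁+m₂ = 0
is flagged undefined. Timing uses R = K/2T with canonical calibration
points (chimpanzee–human 6–7 Mya, orangutan 15, macaque 25, OWM/NWM 35);
`duplication_time(K, calibrate_rate(K, T)) = T` holds to machine
precision and is tested as such.

## What the generators emulate — and what they do not

`simulate_landscape()` produces chromosomes with a blockwise GC track
(Normal(0.41, 0.05) per 500-kb block, truncated), SINEs (300/Mbp, 300 bp)
whose intensity carries a `sine_gc_coupling`-fold odds multiplier
(default 4) in high-GC blocks with the genome-wide mean renormalized,
homogeneous LINEs (60/Mbp, 6 kbp), and an exclusion mask covering ~10%
of each chromosome. Defaults were set once to mimic a primate
euchromatic landscape at desk scale (8 × 12 Mbp): mean GC and Alu/L1
densities are in the range of human chromosome-arm averages, and the
two-level GC→SINE coupling gives the planted-enrichment machinery a
wide, analytically tractable intensity contrast.

`simulate_duplication_history()` plants its enrichment by choosing each
donor's containing GC block with weights λ_b^θ, solving θ by monotone
root-finding so the expected SINE intensity over placed donors equals
`donor_enrichment_E` times the allowed-space mean — the planted
coefficient is exact in expectation, so recovery tests measure estimator
noise, not generator bias. Donor duplicon sizes default to 15–180 kbp
and inserted block sizes to 150–380 kbp (the study-scale ranges);
junction Alus are planted with probability 9/14 to overlap the ±50 bp
window; deletions are lognormal in kbp (meanlog log 5.8, sdlog 1.1,
median 5.8 kbp with a spread covering ~3–80 kbp) with a 1/13 chance of
precise integration.

`simulate_codon_family()` evolves a uniform sense-codon root along
per-group ancestral and tip branches by exact Gillespie simulation:
each single-base codon change has rate κ (transitions) × ω
(nonsynonymous), stop moves have rate zero, and branch lengths are in
expected substitutions per codon at neutrality. Matrix exponentiation is
deliberately avoided — the event-level simulation is exact and fast at
desk scale. A useful identity: a mutation process with ts/tv rate ratio
κ corresponds to a modified-NG site weighting with R = κ/2 (the
transition then carries probability κ/(κ+2) of a random mutation at a
position), which the ω-recovery tests exercise with κ = 2, R = 1.

What passing tests on these generators do **not** show about real data:
the landscapes have no isochore structure, replication-timing
covariates, repeat subfamily age structure or chromosome-specific
architecture; junctions carry no sequence homology signal (only
annotation); codon families have no alignment error, gene conversion,
indels or among-site rate variation. The generators validate the
statistical machinery, not the biology.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; 1-based inclusive input
  is accepted via `one_based = TRUE` on `read_bed()` (genome-browser
  interoperability). Abutting intervals merge — nonredundant-region
  semantics. Zero-length intervals are rejected on read.
* The 10-kbp acceptor flank is collected by *walking* outward base by
  base over the unique mask, concatenating across interruptions, rather
  than by requiring a single gap-free window; both readings of "nearest
  contiguous unique sequence" were defensible, the walk was chosen
  because it always uses the nearest unique bases, and truncation at a
  chromosome end or exhausted unique space is a flag, not an error.
* Repeat classes outside {SINE, LINE, LTR, DNA} map to `"other"` because
  annotation class strings vary by dialect.
* Extreme tail p-values are kept at float precision (scientific
  notation), never truncated to zero.
* Permutation sub-seeds are derived per (region set × feature) from the
  run seed, so results do not depend on test order; all pipeline stages
  derive named sub-seeds from one master seed.
* A proportion pS > 1 (pathway-averaged counts exceeding potential
  sites) marks a pair saturated under either correction; the Z-test is
  then undefined rather than silently NaN.

## Known limitations

The analytic selection Z-test is asymptotic and anticonservative below
roughly 15 synonymous events per comparison. The pooled-scan variance
correction is exact only for star-like within-group genealogies. The KS
null sample pools placements, which ignores the small dependence between
per-region values within one placement set. The NJ implementation is
quadratic-per-iteration and intended for the tens-of-taxa scale of
paralog trees, not for thousands of taxa. None of the published
genome-scale enrichment coefficients are recomputable without the
original assembly, repeat tracks and coordinates; the package instead
demonstrates recovery of known planted effects on synthetic landscapes.
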