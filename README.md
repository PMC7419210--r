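# dupliconevo

Evolutionary analysis of interspersed segmental duplications (SDs) seeded
by a core duplicon, for comparative genomicists studying how duplication
blocks spread through primate genomes and how the gene families they carry
evolve. The package re-implements, as tested and reusable R functions, the
statistical machinery such a study needs:

* **Permutation enrichment.** Are duplication *donor* segments, *acceptor*
  regions and *pre-integration* sites unusually GC-rich or SINE/LINE-rich?
  Observed feature values are compared with a null built from
  length-preserving random placements inside the genome minus SDs,
  centromeres, telomeres and gaps. Each test reports the enrichment
  coefficient *E* = observed / mean(null), a raw p-value
  (two-sample Kolmogorov–Smirnov for GC; upper-tail Z-score
  transformation, *z* = (obs − μ₀)/σ₀, for repeat counts), Bonferroni
  correction over the test family (nine for the canonical 3 region classes
  × 3 features design), and the binomial standard error
  SE = √(p(1 − p)/n) with *n* the number of regions. Tests with
  corrected p + SE ≤ 0.05 are starred.
* **Breakpoint and junction accounting.** ±50 bp repeat classification of
  duplication-transition junctions, deletion sizing at pre-integration
  sites (anchor span on the outgroup assembly, in kbp), and clone-library
  copy-number estimation (positively hybridizing clones / library
  coverage).
* **Molecular evolution.** Modified Nei–Gojobori dN/dS with
  ts/tv-weighted potential sites and pathway averaging; one-tailed
  selection Z-tests on *D* = dN − dS with *Z* = *D*/σ,
  σ = √(var dN + var dS); per-group, per-exon selection scans;
  Kimura two-parameter distances
  K = −½ ln((1 − 2P − Q)√(1 − 2Q)) with delta-method standard errors;
  neighbor-joining trees with column-bootstrap supports; the Tajima
  relative rate test; and duplication timing via R = K/2T.
* **Synthetic data.** Seeded generators with known ground truth for every
  input: repeat-annotated genome landscapes with GC-coupled SINE density,
  duplication histories with a *planted* enrichment coefficient,
  Alu-seeded junctions and lognormal pre-integration deletions, and codon
  paralog families evolved under per-group ω with ts/tv bias κ.

All user-facing functions take and return tibbles (trees are `ape::phylo`
objects), chain with the pipe, and have `tidy()`/`glance()`/`autoplot()`
methods where a fitted object warrants them.

## Worked example

Plant a 1.5-fold SINE enrichment at 63 donor segments, run the permutation
test, classify junctions, and scan simulated paralog groups for selection:

```r
library(dupliconevo)

sim  <- simulate_landscape(seed = 42)                      # 8 x 12 Mbp genome
hist <- simulate_duplication_history(sim, n_blocks = 63,
                                     donor_enrichment_E = 1.5, seed = 43)
enr  <- run_enrichment(hist$landscape,
                       list(donors = hist$donors, acceptors = hist$acceptors),
                       n_permutations = 500, seed = 44)
format_enrichment_table(enr)
#>   role      n_regions gc                          sine
#> 1 donors           63 1.06, 2.33e-07 ± 6.1e-05 *  1.50, 2.58e-10 ± 2e-06 *
#> 2 acceptors        63 1.03, 0.348 ± 0.06          1.06, 0.258 ± 0.055
#>   line
#> 1 1.04, 0.218 ± 0.052
#> 2 1.00, 0.516 ± 0.063
```

The donors recover the planted coefficient (E = 1.50, starred after a
six-test Bonferroni correction); the acceptors, placed uniformly here, sit
at E ≈ 1. GC co-enriches mildly (E = 1.06) because the generator couples
SINE density to high-GC blocks.

```r
fam  <- simulate_codon_family(c(HSA = 4, CJA = 4),
                              omega_per_group = c(HSA = 3, CJA = 0.3),
                              n_codons = 300, seed = 45)
group_selection_scan(fam$sequences, fam$groups)
#>   group pooled_dN pooled_dS pooled_Z  pooled_p significant
#> 1 HSA      0.272     0.114      6.70  1.01e-11 TRUE
#> 2 CJA      0.0284    0.0871    -3.90  1.00     FALSE
```

The ω = 3 group shows the expected excess of nonsynonymous substitutions
(dN > dS, one-tailed p ≈ 10⁻¹¹); the purifying group does not.

```r
rate <- calibrate_rate(K = 0.07, T_mya = 35)   # 0.001 subs/site/My
duplication_time(0.05, rate)                   # 25 Mya
```

`run_pipeline()` chains all stages (simulate → enrich → junctions →
selection scan → NJ/bootstrap → timing) from one seed and returns the
report tables plus a reproducibility manifest.

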