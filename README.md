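# cnedrift

Detecting relaxed purifying selection on conserved non-coding elements
(CNEs) across a species phylogeny.

When a lineage loses a trait — Antarctic icefishes losing erythrocytes and
hemoglobin is the canonical case — selection on the regulatory elements of
that trait relaxes, and the footprint is an elevated substitution rate
concentrated on the branch where the trait disappeared and on the CNEs near
the trait's genes. `cnedrift` implements the full inference chain for
detecting that footprint, plus the two companion analyses that interpret
it, and a synthetic-data module that generates every input with planted
ground truth so the pipeline is testable end to end:

* **Phylogenetic core** — JC/HKY substitution models, Felsenstein pruning
  log-likelihoods, neutral-model fitting from filtered concatenated
  elements (≥ 250 bp, ≥ 85% coverage in every species), and per-locus
  maximum-likelihood branch lengths on the fixed species topology.
* **Relative evolutionary rates (RER)** — per branch and per locus, with
  square-root transform, per-locus scaling, and a heteroskedasticity
  correction (inverse-variance weights from an isotonic variance–mean fit);
  RER > 0 means a branch evolved faster than the genome-wide expectation at
  that locus.
* **Acceleration test** — a one-sided likelihood-ratio test of a
  pre-specified foreground branch against the neutral model, with the
  boundary null ½χ²₀ + ½χ²₁ and the fourth-root statistic ΔlnL¹ᐟ⁴ used for
  set-level enrichment.
* **Regulatory domains** — GREAT-style basal-plus-extension assignment of
  CNEs to genes: 5 kb/1 kb basal windows around each TSS, flanks extended
  up to 1 Mb or until a neighbouring basal window.
* **Enrichment** — bootstrap Z-scores of mean RER and SUMSTAT
  (sum of ΔlnL¹ᐟ⁴) with empirical p-values over 1,500 resamples,
  Benjamini–Hochberg FDR, and a one-tailed high-latitude vs sub-Antarctic
  lineage contrast.
* **Mutation screen** — gene assembly from exons, truncating-variant calls
  (frameshift / premature stop / whole-gene deletion) with read-support
  rules, mapping of species missense variants onto human clinical sites,
  pleiotropy scores from a phenotype ontology, and the loss-of-function ×
  pleiotropy exact test.
* **Shape metrics** — segmentation of stained blood-smear images,
  Crofton-perimeter circularity C = 4πA/P², solidity, the printed filter
  chain (70–150 µm², C ≥ 0.80, solidity ≥ 0.93) and the rank-sum
  circularity comparison.

See `vignettes/cnedrift-methods.Rmd` for the models, parameter choices and
design decisions.

## Worked example

Simulate a 20-species clade with a foreground branch, 300 CNEs of 300 bp of
which 50 evolve 4× faster on that branch, map CNEs to 100 genes, and score
20 ontology terms (one planted on the genes near the shifted CNEs):

```r
library(cnedrift)
res <- run_planted_analysis(sim_config(seed = 7))
head(res$terms[order(-res$terms$z), c("term_id", "n_cnes", "z",
                                      "sumstat_p", "q")], 5)
#>         term_id n_cnes      z sumstat_p      q
#> 20 TERM_planted     41  5.577  0.000666 0.0133
#> 18 TERM_decoy18      8 -0.539  1.000000 1.0000
#> 5  TERM_decoy05      7 -0.739  1.000000 1.0000
#> 16 TERM_decoy16      9 -0.798  1.000000 1.0000
#> 3  TERM_decoy03     11 -1.030  1.000000 1.0000
```

The planted term ranks first by a wide margin: its CNEs have elevated
foreground RER (Z = 5.6 against bootstrap resamples of equal size) and its
summed ΔlnL¹ᐟ⁴ exceeds all but one in ~1,500 resampled sums
(empirical p = 0.00067, q = 0.013 after FDR across the 19 scored terms);
every decoy stays at q = 1.

Erythrocyte morphology on synthetic masks — 100 circular cells (the
spherocytic class) against 100 two-to-one ellipses (normal oval
erythrocytes), measured, filtered and compared:

```r
cfg <- sim_config(seed = 7)
sm <- simulate_masks(cfg)
meas <- filter_particles(measure_particles(sm$image, cfg$pixel_size_um))
#> median C: circles 0.999, ellipses 0.842; W = 10000, p = 2.37e-34
```

A perfect circle has C = 1; the 2:1 ellipse sits at the Ramanujan-derived
0.841, and the rank-sum test separates the populations at p < 0.001.

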