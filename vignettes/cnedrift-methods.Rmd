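---
title: "Detecting relaxed selection on conserved non-coding elements: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting relaxed selection on conserved non-coding elements: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cnedrift)
```

## The scientific problem

When a lineage loses a trait — the textbook case being Antarctic icefishes,
which survive without erythrocytes and hemoglobin — purifying selection on
the genetic program behind that trait is expected to relax. The footprint of
that relaxation is an elevated substitution rate, concentrated on the branch
where the trait was lost and in the genomic elements that regulated the
trait. `cnedrift` implements the comparative-genomics machinery needed to
detect and localise that footprint: per-locus evolutionary rates on a fixed
species tree, a branch-specific acceleration test, assignment of conserved
non-coding elements (CNEs) to the genes they plausibly regulate, and
gene-set (ontology) enrichment by bootstrap resampling. Around the genomic
core sit two companion analyses: a loss-of-function screen with pleiotropy
scoring (why do most erythroid *coding* genes survive?), and erythrocyte
shape quantification from stained blood-smear images (spherocytosis versus
normal oval cells).

Every input has a synthetic generator with planted ground truth, so the
whole pipeline is testable end to end without any external download.

## Likelihood machinery

Substitution models are JC and HKY (equilibrium frequencies $\pi$,
transition/transversion ratio $\kappa$), with the rate matrix normalised to
one expected substitution per unit time so branch lengths are in expected
substitutions per site. The likelihood of an alignment on a tree is computed
by Felsenstein pruning, vectorised over unique site patterns. Because every
model used is reversible, $P(t)$ comes from a symmetrised spectral
decomposition computed once per model; this also gives each branch-length
optimisation a closed-form objective
$\ell(t) = \sum_s w_s \log \sum_k e^{\lambda_k t} C_{ks}$
whose gradient and curvature are analytic, so per-branch optimisation uses
safeguarded Newton steps rather than derivative-free search.

Per-locus branch lengths are estimated by coordinate sweeps over branches:
partial likelihoods above and below each edge are cached at the start of a
sweep, each branch solves a one-dimensional problem against those caches,
and sweeps repeat until the log-likelihood stops improving (relative
tolerance $10^{-6}$, at least 2 sweeps). Because within-sweep caches go
stale as branches move, a sweep is not guaranteed monotone; the best sweep
is kept and the loop stops on the first non-improving sweep. On 10 kb
simulated alignments the optimum matches `phangorn::optim.pml` to six
decimal places (this is a test). Branch lengths are capped at 10
substitutions/site; data past the JC saturation ceiling (three quarters of
sites differing) drive lengths to the cap, which is reported in `at_bound`.

Gaps, `N` and all other ambiguity codes are missing data (partial likelihood
1 in every state). A species absent from a locus keeps the topology intact —
its subtree is marginalised — and its terminal branch is reported `NA`.

## Neutral model

`fit_neutral_model()` mirrors standard practice for building the background
(neutral) model from conserved elements: elements shorter than 250 bp or
with any species under 85% coverage are excluded, survivors are
concatenated, and branch lengths plus $\kappa$ (with empirical base
frequencies) are fit jointly. The concatenation is capped (default 50 kb in
the function, 20 kb in the pipeline) — parameter uncertainty at that size is
already far below the per-element noise that dominates downstream
statistics.

The pipeline fits the neutral model twice. Elements carrying a genuine
foreground acceleration inflate the fitted foreground branch by roughly the
case-fraction-weighted mean of their scale, which both miscalibrates the
null and dilutes power. After a first acceleration scan, the model is refit
on elements with $p > 0.25$ and the scan repeated. Under a global null this
exclusion removes about an eighth of elements and biases the foreground
branch slightly downward; the null-control tests below confirm the effect on
false positives is negligible at study scale.

## Relative evolutionary rates

`compute_rer()` follows the standard RER recipe with the parameters
`transform = "sqrt"`, `weighted = TRUE`, `scale = TRUE`, `cutoff = 0`:

1. branch lengths below `cutoff` become missing (0 retains everything
   non-negative);
2. each locus row is divided by its row sum, removing locus-specific overall
   rate;
3. the per-branch expectation is the across-locus mean of scaled lengths;
4. locus values and expectations are square-root transformed;
5. each locus is regressed (intercept + slope) on the expectations and RERs
   are the per-locus standardised residuals.

Long branches accumulate more substitution noise than short ones, so step 5
is weighted: squared residuals from an unweighted first pass are pooled
across loci, binned by fitted value into ten equal-count bins, the bin means
get an isotonic (monotone non-decreasing) fit, and weights are the inverse
of that variance function. The testable meaning is that binned RER variances
for short, medium and long branches stay within a factor of two of each
other on neutral simulations, which the suite asserts. A locus needs at
least 4 observed branches to receive RERs; a branch whose expectation is
degenerate (all zeros) is dropped with a warning.

Note a sampling caveat: RERs are standardised within locus, so each branch's
across-locus mean has standard error $1/\sqrt{L}$. At desk scale
($L = 100$ loci) branch means of $\pm 0.2$ are ordinary noise; only at
genome scale do per-branch means pin down near zero.

## Acceleration test

`accel_lrt()` tests one pre-specified (foreground) branch per element. The
null holds every branch at the neutral length; the alternative maximises
over a single multiplier $\lambda \in [1, 100]$ on the foreground branch
(one-sided: acceleration only; a config switch scales the whole descendant
subtree instead). Since the null sits on the boundary of the parameter
space, $2\Delta\ln L$ is referred to the mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$: $p = 1$ when the ratio is zero, else
half the upper $\chi^2_1$ tail. Calibration is verified empirically: at
$\lambda = 1$, 500 elements of 300 bp give a $p < 0.05$ fraction inside the
exact binomial 99% interval around 0.05; at $\lambda = 4$ and 500 bp, power
exceeds 0.8. The enrichment statistic uses the fourth root
$\Delta\ln L^{1/4}$, which tames the long right tail so that a set-level sum
is not dominated by a handful of extreme elements.

## Regulatory domains and CNE assignment

CNEs are linked to genes by the basal-plus-extension rule: every gene owns a
strand-aware basal window (5 kb upstream, 1 kb downstream of the TSS), and
each flank extends up to 1 Mb or until it meets another gene's *basal*
window — never another gene's extension, and never shrinking below its own
basal. All coordinates are 0-based half-open. A CNE is assigned to every
gene whose extended domain contains its midpoint; several genes can share a
CNE, and a CNE beyond 1 Mb + basal from every TSS stays unassigned. The
midpoint rule (an any-overlap flag exists) avoids double counting long
elements straddling a boundary, and half-open intervals make boundary ties
unambiguous: a midpoint exactly on a domain end is outside. Assignments are
verified against a brute-force all-pairs containment scan on random genomes.

## Enrichment statistics

Two set-level statistics, both by bootstrap resampling with replacement at
the term's own size ("equivalent bin sizes"), 1,500 replicates by default:

* **Z-score** of the term's mean per-unit score (e.g. foreground RER per
  CNE) against the mean and sd of resampled means. $Z > 0$ is accelerated,
  $Z < 0$ constrained.
* **SUMSTAT**: the term's summed $\Delta\ln L^{1/4}$ against resampled
  sums, with the tie-inclusive empirical p-value
  $(1 + \#\{\text{resample} \ge \text{obs}\})/(1 + B)$ — never exactly
  zero, and exactly 1 on degenerate constant input.

P-values across terms are corrected by Benjamini–Hochberg (q-values). The
resampling unit is the CNE for CNE analyses and the gene for coding
analyses; the minimum term size defaults to 1,000 CNEs at genome scale and
is configurable (the desk-scale pipeline uses 5). Gene-set propagation up
the ontology DAG is standard practice and is applied in the pleiotropy
module's descendant closures; the synthetic ontology is flat apart from its
root, so the planted-term analyses do not depend on it.

The high-latitude/sub-Antarctic contrast averages RER over a term's CNEs per
extant branch and applies a one-tailed two-sample t-test (HA > SA), pooled
variance by default with a Welch flag. With identical groups the one-tailed
p is exactly 0.5. At 10 branches per class and a one-sd shift the analytic
power is 0.69, and the simulated power in the test suite matches that
benchmark.

## Mutation screen and pleiotropy

Gene sequences are rebuilt by concatenating single-copy exons in reference
order (isoform duplicates collapse; a missing exon leaves an `N`
placeholder). Truncation calls follow three rules: an indel whose length is
not divisible by 3 is a frameshift; a substitution creating a stop codon
strictly before the terminal codon is nonsense; zero coverage across every
exon of a gene — while the same species has coverage at other genes — is a
whole-gene deletion. Frameshift and nonsense calls require at least 3
supporting reads. "Fixed" is operationalised as all covering reads
supporting the variant (a configurable fraction covers pooled-sample
noise); a whole-gene deletion is fixed by definition.

Species missense variants are mapped onto human clinical sites only at
alignment columns where the inferred ancestral residue equals the human
residue — the guard against non-homologous sites. The ancestral state is the
majority residue (at least two-thirds) among designated outgroup species;
columns without such a majority are skipped.

The pleiotropy score counts a gene's phenotype annotations outside the
hematopoietic system: annotations under the hematopoietic root, in the
excluded list (indirect phenotypes secondary to anemia — pallor, blood
chemistry, organ size, spleen abnormalities), or below an excluded term are
removed; the score is the count of what remains, so 0 means purely
hematopoietic. Expression bias uses a fold threshold (default 2): a gene is
erythroid-biased when its erythrocyte expression is at least twice the
maximum across other hematopoietic lineages, and marrow-restricted
analogously across organs. The association between loss-of-function and low
pleiotropy is tested with the two-sided conditional exact (hypergeometric)
test; the odds ratio is reported with the Haldane 0.5 correction when a cell
is empty (the correction never touches the p-value).

## Shape metrics

Segmentation reproduces a standard smear-quantification chain: Gaussian
blur (sigma 1 px), rolling-ball background subtraction — implemented as
grayscale opening with a disc of the configured radius (default 7 px) on the
inverted image, a documented functional stand-in with the same
parameterisation — contrast normalisation, the minimum-method histogram
threshold (smooth the 256-bin histogram until exactly two modes remain, cut
at the valley; a unimodal histogram is an error suggesting a manual
threshold), then morphological opening, closing and hole filling.

Measurement uses 8-connected components, drops particles touching the 1-px
border, and computes area (pixel count times pixel size squared),
circularity $C = 4\pi A / P^2$ and solidity (area over convex-hull area,
hull taken over pixel corners so convex particles stay at or below 1). The
perimeter uses a Crofton-style 4-direction intercept estimator,
$P = \tfrac{\pi}{8}\,(n_0 + n_{90} + (n_{45} + n_{135})/\sqrt2)$, because
naive pixel-edge counting biases $C$ far below 1 for circles: a rasterised
circle of radius 30 px measures $C \approx 0.98$ here, and a 2:1 ellipse
$C \approx 0.84$, matching the Ramanujan-perimeter value 0.841. Filters
retain particles with area 70–150 µm², $C \ge 0.80$ and solidity
$\ge 0.93$; group comparison is the two-sample Wilcoxon rank-sum test on
retained circularities. (The figure legend this analysis mirrors names a
signed-rank test, but the two samples are independent cells from different
individuals, so the rank-sum form is the defensible choice.)

## The synthetic-data generators

The generators define the study conditions; their defaults are fixed and
are not tuned per analysis.

* **Tree**: pure-birth (Yule) topology on 20 tips, rescaled so the crown age
  is uniform in 18.6–23.9 Ma — the calibration window for the clade the
  package models. One internal branch subtending roughly a quarter of the
  tips is the foreground ("icefish-ancestor") branch; its descendant tips
  are labelled HA, the rest SA. A global clock of 0.01 substitutions per
  site per Ma converts time to expected substitutions, giving root-to-tip
  paths of ~0.2 substitutions/site — the weakly-constrained regime typical
  of conserved non-coding elements.
* **Loci**: 300 alignments of 300 bp evolved under HKY
  ($\pi = (0.3, 0.2, 0.2, 0.3)$, $\kappa = 2$); 50 of them have the
  foreground branch length multiplied by 4. Rate shifts are branch-length
  multipliers — exactly the alternative the LRT and RER methods assume. No
  indels are simulated; an optional per-species dropout rate (default 0)
  exercises missing-branch handling.
* **Annotations**: 100 TSSs and 300 non-overlapping CNE intervals (one per
  locus) on a 400 Mb chromosome. The genome length is the one free
  geometric choice: with 1 Mb maximum extensions, gene spacing must exceed
  ~2 Mb or regulatory domains tile the chromosome end to end, every CNE
  joins one or two domains, and the planted term degenerates toward the
  whole universe. At 4 Mb spacing domains cover about half the genome, each
  CNE belongs to at most one gene, and the planted term — defined as
  exactly the genes whose domains contain shifted CNEs — is a proper,
  majority-shifted subset. Decoy terms draw from the remaining genes
  without replacement across terms (disjoint negative controls) so that a
  decoy can never inherit planted signal and decoy Z-scores are not
  correlated through shared genes.
* **Pileups**: reference coding sequences free of internal stops, per-exon
  coverage rows at the configured depth, and planted variants — fixed
  variants supported by every covering read, polymorphic ones by a binomial
  draw at their allele fraction, whole-gene deletions by zero coverage at
  every exon.
* **Masks**: non-touching filled ellipses on a jittered grid, one particle
  per cell; semi-axes $r\sqrt{a}$ and $r/\sqrt{a}$ preserve area across
  aspect ratios. Defaults (radius 24 px at 0.25 µm/px) give cell areas of
  ~113 µm², inside the 70–150 µm² filter, and keep the solidity
  discretisation bias (~$1/r$) well clear of the 0.93 threshold. A
  grayscale mode (darker shapes, Gaussian noise) exercises the segmentation
  path with smaller cells than the background-subtraction disc.

All generators are fully determined by the configuration seed.

### What the generators do and do not emulate

They reproduce the statistical structure the methods assume: a calibrated
ultrametric tree, HKY substitution, single-branch rate shifts, domain-based
CNE-to-gene linkage, read-support pileups, and geometric cell shapes. They
do not emulate alignment error, indels, GC-content variation, capture-data
missingness structure (dropout is a free parameter, not calibrated),
ontology DAG depth, or image artifacts like touching cells and uneven
staining. Passing tests therefore demonstrate correctness of the inference
machinery under its own model, not robustness to every failure mode of real
capture data.

## Problem sizes and numerical choices

The test suite and acceptance analyses run at fixed desk-scale sizes chosen
to keep the full pipeline in the tens of seconds per replicate: 20 species,
300 x 300 bp loci, 1,500 bootstrap replicates, 10 seeded replicates for the
end-to-end recovery and null-control properties, 500 elements for LRT
calibration, 100 random genomes for the assignment oracle, and 100 cells
per shape class. Branch-length estimation tolerance is $10^{-6}$ relative
log-likelihood; the acceleration optimiser tolerance is $10^{-6}$ on
$\lambda$; the branch-length cap is 10 substitutions/site; empirical
p-values carry the +1 correction; BH q-values clip at 1.

## Known limitations

* Coordinate-wise branch optimisation with per-sweep caches trades
  guaranteed monotonicity for speed; the safeguard (keep the best sweep,
  stop on non-improvement) has matched the reference optimiser everywhere
  tested, but pathological flat likelihoods could stop one sweep early.
* The acceleration test scales a single pre-specified branch; testing many
  branches or clade-wide shifts requires the subtree switch and care with
  multiplicity.
* The heteroskedasticity correction is a binned isotonic variance fit — a
  documented, testable stand-in for the correction implemented in the
  reference RER tool, not a line-by-line reproduction of it.
* Pleiotropy scores count retained annotations, not distinct organ systems;
  genes annotated at different ontology granularities are not harmonised.
* The rolling-ball background subtraction is a morphological-opening
  stand-in; on images whose cells are larger than the disc the subtraction
  attenuates cell interiors, as the original plugin also does in that
  regime.
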