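---
title: "Two-stage genomic analysis of CBSD resistance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage genomic analysis of CBSD resistance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cassavaGS)
```

## The problem

Cassava brown streak disease (CBSD) is scored in breeding trials on an
ordinal 1–5 scale, on leaves at 3, 6 and 9 months after planting and on
storage roots at harvest. Resistance is quantitative, heritability varies
strongly with location and disease pressure, and part of the resistance in
East African germplasm travels on a *Manihot glaziovii* introgression
segment on chromosome 4, with a second QTL cluster on chromosome 11.
`cassavaGS` implements the full two-stage analysis such data call for:

1. **Stage one** — trial-design linear mixed models per panel and
   location, yielding clone BLUPs, their prediction error variances
   (PEV), de-regressed BLUPs and entry-mean broad-sense heritability.
2. **Stage two** — marker QC, genomic relationship matrices, SNP
   heritability, PCA, mixed-linear-model association with
   leave-one-chromosome-out (LOCO) kinship, seven genomic prediction
   models under cross-validation, introgression-segment detection from
   ancestry-informative (AI) SNPs, and LD-score diagnostics.

Everything is exercised end-to-end on a synthetic breeding-panel
generator with known genetic architecture, so that each stage's
statistical behaviour is testable without any field data.

## Stage one: trial models and de-regression

For a replicated alpha-lattice trial the model is

y = Xβ + Z_clone c + Z_block b + Z_range r + ε,

with fixed effects for the population mean and location (and optionally a
CMD-severity covariate, used to strip a co-segregating cassava mosaic
disease QTL out of the de-regressed BLUPs before association), and
random clone, incomplete-block and range effects, blocks and ranges
nested in location–rep. The augmented-design model for the unreplicated
panel drops the range term and adds a fixed check effect. Fitting is
REML via `lme4::lmer`; ordinal scores are analysed as numeric, the
standard practice for severity scales.

De-regression removes the shrinkage of BLUPs before they are used as a
second-stage response:

dereg = BLUP / (1 − PEV/σ²_c).

The denominator is the BLUP's reliability. It can approach zero for
clones observed in very few plots, in which case the ratio explodes;
clones with reliability ≤ 0.05 (the `reliability_floor` argument) are
flagged and excluded rather than returned. Entry-mean heritability uses
the plant-breeding convention

H² = σ²_c / (σ²_c + σ²_other/ r̄),

with r̄ the harmonic mean of plots per clone and σ²_other the sum of the
non-clone random variances. The formula basis (entry means) is standard;
the specific apportioning is our choice and is applied consistently in
the generator's calibration and the estimator.

## Stage two

**Marker QC.** The cascade removes markers with more than 60 % missing
calls, then imputation quality AR² not above 0.3, then MAF not above
0.01 (association scans re-filter at MAF 0.05). All comparisons are
strict, so a marker exactly at a threshold is removed; the order is
configurable because only the thresholds, not their order of
application, are canonical.

**GRM and SNP heritability.** The VanRaden construction
G = WW′ / (2Σp(1−p)) with observed allele frequencies and 2p centering;
fractional (imputed) dosages are accepted everywhere, with frequencies
taken as mean dosage / 2. SNP heritability comes from single-kernel REML
of y = μ + g + e, g ~ N(0, Gσ²_g), solved on the eigenbasis of G so the
variance-ratio profile costs O(n) per evaluation after one
decomposition. Non-PSD kernels are bent by clipping negative
eigenvalues, with a warning.

**MLMA-LOCO.** For each chromosome the variance components are
re-estimated once under a kinship built from all other chromosomes
(computed efficiently as the whole-genome cross-product minus the
chromosome's own block), and each marker on the chromosome is tested by
GLS under that fit — the candidate marker therefore never contributes to
its own kinship. One deliberate choice: the per-marker test re-estimates
the residual scale from the marker model and refers the statistic to a
t distribution (df = n − 2) instead of the more common Wald chi-square
with plugged-in null variances. The two are indistinguishable at GWAS
sample sizes, but the t form reduces *exactly* to ordinary least squares
when the kinship is the identity, which gives the implementation a sharp
oracle: the test suite checks per-marker p-values against `lm()` to
|Δlog10 p| < 0.01. Single-marker variance explained is reported as the
conventional 2p(1−p)β²/Var(y) with Var(y) the variance of the
de-regressed BLUPs; the Bonferroni threshold is −log10(α/m), which at
α = 0.05 and m = 41,530 post-QC markers prints as 5.9.

**Genomic prediction.** Seven models behind one cross-validation
harness:

* `gblup` — single-kernel GBLUP; untrained clones are predicted through
  their genomic relationships with the training set.
* `mk_gblup` — chromosome-partitioned multi-kernel GBLUP (one VanRaden
  kernel per focal chromosome, e.g. 4 and 11, plus the rest of the
  genome), the GWAS-guided configuration. Per-kernel prediction
  components sum exactly to the total, so each kernel's contribution to
  accuracy is the correlation of its component with the validation
  values.
* `rkhs` — Gaussian kernels K_ij = exp(−d_ij·θ) over the six-bandwidth
  grid 5e-7, 5e-5, 5e-4, 5e-3, 0.01, 0.05, fitted jointly with
  REML-estimated weights (kernel averaging). d_ij is read as the
  *squared* Euclidean distance between dosage rows — the convention of
  the kernel-averaging literature — with a flag for plain Euclidean.
* `bayesA`, `bayesB`, `bayesCpi`, `bl` — Gibbs samplers (compiled code)
  under scaled-t, point-mass + scaled-t, point-mass + Gaussian with the
  mixing proportion sampled, and double-exponential priors. Hyperpriors
  follow the family's usual defaults: 5 prior degrees of freedom, scales
  matched so the prior mode attributes half the phenotypic variance to
  markers; defaults of 6,000 iterations with 1,000 burn-in.
* `rf` — Random Forest regression on dosage columns with ntree = 500
  and mtry = 300 (clipped to the marker count when fewer markers are
  available), a total-genetic-value predictor.

The multi-kernel engine is AI-REML with damped steps and a monotone
EM-REML fallback; all-zero kernels are unidentifiable and are fixed at
variance zero, and when a single informative kernel remains the fit
collapses to the exact single-kernel eigen-profile path. Convergence is
declared on a relative restricted-likelihood change of 1e-6; variances
are floored at 1e-8 of the phenotypic variance.

Accuracy is the plain Pearson correlation between predictions and the
held-out clones' de-regressed BLUPs — not divided by √H², matching how
"predictive accuracy" is usually reported for these trials. The default
scheme is repeated k-fold within the combined panels; a `cross_panel`
scheme (train on one panel, predict the other) covers the
cross-generation use case.

**Introgression calling.** AI SNPs — fixed for different alleles in pure
*M. esculenta* and *M. glaziovii* — are matched to the marker map by
(chromosome, position) with allele orientation reconciled so dosage
counts the glaziovii allele (swapped records are flipped to 2 − d,
irreconcilable ones dropped). Per chromosome the AI SNPs are tiled into
non-overlapping 20-SNP windows in bp order (a trailing remainder is
dropped); each genotype is classified G/G, G/E or E/E and the window is
called to the most common class iff its proportion is **at least** twice
the runner-up — a tie at exactly 2× is a call, because "at least twice"
includes equality. Missing genotypes leave the denominator; windows with
fewer than 10 informative AI SNPs are NoCall (a threshold we chose;
configurable). Contiguous non-EE calls merge into segments; NoCall
breaks a run. No HMM smoothing is applied.

**LD scores.** Genotypic r² (squared Pearson correlation of dosage
vectors) with the small-sample correction r² − (1−r²)/(n−2), summed over
± 1 Mb including the self-pair, so independent markers contribute zero
in expectation and a marker alone in its window scores exactly 1. The
window is ± 1 Mb (2 Mb span), with both the width and the self-pair
inclusion configurable.

## The synthetic generator

`sim_config()` defaults encode the study conditions at desk scale: two
panels of 300 and 600 clones (the field panels' 1:2 ratio), five
chromosomes labelled 1, 2, 3, 4 and 11 with 1,000 markers each over
30 Mb, three locations per panel with an alpha-lattice design
(2 reps, 25-clone blocks) for Panel 1 and an augmented design (6 checks
in every 25-clone incomplete block) for Panel 2, target entry-mean
heritabilities per location spanning 0.25–0.60 (the low-to-intermediate
range such trials report), a donor segment on chromosome 4 carried by
25 % of clones with a protective latent effect, a three-QTL cluster on
chromosome 11, and a polygenic background of 200 loci.

Design choices worth knowing:

* **LD by founder-block copying.** Gametes copy 25-marker blocks from a
  pool of 40 founder haplotypes whose allele frequencies are drawn from
  a U-shaped Beta(0.3, 0.3). This produces block-structured local LD
  sufficient for LOCO and LD-score behaviour; it is not a coalescent
  model and has no recombination-map realism.
* **Latent-threshold scores.** Plot values are generated on a latent
  scale (location mean + per-location genetic value + block/range
  effects + residual) and cut at four thresholds into the 1–5 score, so
  the generator produces both the ordinal surface the field book shows
  and the latent truth the oracle tests need. Non-genetic variance is
  scaled so the per-location entry-mean H² matches the configuration on
  the latent scale; thresholding attenuates the ordinal-scale H² by
  roughly 5–10 %, which the round-trip tests absorb within their ±0.1
  band.
* **Window-aligned donor segment.** The realized introgression interval
  is snapped to 20-AI-SNP window boundaries, so window-level ancestry
  truth is exact; unaligned boundaries would make truth ill-defined for
  straddling windows. Heterozygous carriers arise from pairing one donor
  and one recipient gamete, with the per-gamete donor probability solved
  from the requested carrier frequency.
* **QTL anchoring.** Configured QTL positions are anchored to the
  nearest *segregating* marker (MAF ≥ 0.05); a monomorphic QTL would
  contribute no variance and silently break the stated architecture.
* **Between-location and between-trait correlations** are single
  parameters (defaults 0.6 and 0.7): per-location genetic values are a
  √ρ-weighted mix of the clone's breeding value and an independent
  deviation. Field GxE is richer than this exchangeable structure.

What passing tests on this generator do **not** show: performance under
real GBS missingness patterns, imputation error, pedigree structure,
population stratification (the generator draws all clones from one
founder pool — its PCA shows no clusters by design), or multi-year
effects.

## Validation design for the non-additive model ordering

The test suite checks the qualitative model ordering this analysis
family reports: additive shrinkage models (GBLUP, BayesC-pi) and RKHS
agree on a purely additive trait, while RF and RKHS beat GBLUP on a
non-additive one. The non-additive validation trait combines a focal
epistatic pair (the product of two mid-frequency loci) with polygenic
dominance (50 loci), at high heritability and a deliberately small
marker panel (180 markers, 600 clones). The small panel matters: a
genome-wide Gaussian kernel sees non-additive structure through overall
dosage distance, and a two-locus signal diluted across thousands of
markers is invisible to it at any realistic training size, whereas
Random Forest can find a strong pair at any panel width. The chosen
sizes give both model classes the power to express their advantage in
ten seeds; the ordering itself, not its magnitude, is the tested claim.

## Numerical choices and degenerate inputs

* Single-kernel REML profiles log(σ²_e/σ²_g) on a 25-point grid over
  [−12, 12] refined by Brent search (tolerance 1e-8); boundary fits
  (pure-noise or noise-free responses) land on the grid ends.
* Constant responses short-circuit to zero variance components and zero
  BLUPs; de-regression refuses σ²_c ≤ 0.
* Kernels are checked for PSD-ness and bent (eigenvalue clipping) with a
  warning; zero kernels in a multi-kernel fit are fixed at variance 0.
* Monomorphic markers contribute nothing to GRMs, are excluded from LD
  scores with a log, and error as LD index SNPs.
* Gibbs samplers run on R's RNG stream, so `set.seed()` gives bit-identical
  posterior means; a non-finite draw aborts with the iteration index.
* Chromosome naming is reconciled before GFF3 annotation; fully
  disjoint naming errors out listing the unmatched names.

## Problem sizes

The shipped tests and the acceptance script use the generator's default
downscale (900 clones × 5,000 markers) for calibration-style checks and
smaller panels (180–2,000 markers, 180–600 clones) for model-comparison
checks, with 10 seeds wherever a mean or a win-rate is asserted. These
sizes were chosen so every distributional claim has visible power at
desk scale; all of them are configuration values, not constants.

## Known limitations

* Stage one has no spatial row/column modelling and assumes homoscedastic
  residuals across locations; location is fixed and GxE is not modelled
  beyond independent location deviations in the generator.
* The MLMA is single-marker; no conditional/joint analysis.
* De-regressed BLUPs are pooled across panels for the combined analysis
  (per-panel fits, pooled outputs); a joint two-panel fit is possible by
  passing the combined table to `reml_fit` but is not the default.
* Introgression calling has no HMM smoothing and assumes the AI catalog
  is trustworthy; it identifies no new diagnostic SNPs.
* Weighted multi-kernel RKHS is as good as its bandwidth grid; the grid
  is the literature's but is exposed as an argument.
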