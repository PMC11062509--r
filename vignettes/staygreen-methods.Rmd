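---
title: "Methods: thermal-time stay-green scoring and its genetic dissection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal-time stay-green scoring and its genetic dissection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staygreenr)
```

## The problem

Stay-green — delayed post-anthesis canopy senescence — is a yield and
stress-tolerance trait in cereals. Scoring it across a diverse panel is
confounded by flowering-date differences: at any calendar date, an
early-flowering accession has simply been senescing longer. This package
scores senescence on a thermal-time axis (accumulated temperature, AT) and
corrects the residual between-class offset, producing stage-wise relative
stay-green scores (RSGS) that are comparable across flowering classes and
usable as mixed-model GWAS phenotypes.

## From rasters to index trajectories

Raw digital numbers are converted to reflectance with a single scalar gain
per band per flight, `gain = panel_reflectance / mean(panel DN)`, from a
calibration panel photographed in the scene. The four indices (NDVI,
GNDVI, NDRE, OSAVI) are computed **per pixel and then averaged per plot**.
The alternative — index of the mean reflectances — differs in general
because the indices are ratios; a test pins the implemented order against
a scalar-loop oracle. OSAVI uses the standard soil constant L = 0.16
including the (1+L) numerator factor; the index definitions sit in
`si_definitions()` so alternates can be swapped.

The canopy mask is built **once**, from the NDVI of the anthesis flight,
at threshold 0.6 (taken as ≥, a choice the data source leaves open), and
reused for all later flights. Plot rectangles are 0-based, half-open pixel
rectangles with pixel-center membership; geo-registration is assumed done
upstream and is out of scope. A plot whose mask intersection is empty is
missing (never zero), with a warning.

## RSGS algebra

With `Index_anthesis` the anthesis-flight value (the maximum-greenness
reference, scored 100) and `Index_Si` the value at stage Si:

* `RSS_Si  = (Index_anthesis − Index_Si) / Index_anthesis × 100`
* `RSGS_Si = 100 − RSS_Si`
* `RSGS_Si_corrected = 100 − k_i · RSS_Si`, with
  `k_i = AT(MF at Si) / AT(class at Si)` so `k_i = 1` for mid-flowering
  accessions at every stage.

RSS may be negative (index above the anthesis baseline, e.g. sensor
noise); it is retained and flagged rather than clamped so the
`RSS + RSGS = 100` identity holds exactly, and because the correction is a
per-class constant it preserves within-class rankings. The ratio form also
makes the corrected score invariant to any uniform rescaling of an
accession's index values.

Accumulated temperature is the sum of daily means over days *after*
anthesis up to and including the target day (exclusive of the anthesis day
itself). Stages are assigned per accession to the flight whose AT is
nearest the stage boundary, ties to the earlier date, with a default
tolerance of 60 °C·day — beyond it the stage is left missing with a
warning. The default boundaries S1–S4 = 300, 400, 550, 700 °C·day place
the transition to fast senescence just past 400 °C·day, consistent with
mealy-ripe acceleration; exact per-class stage temperatures are
trial-specific, so the boundaries are fully configurable. Flowering
classes (EF/MF/LF) are input labels, by default a tercile split of
anthesis dates; k is computed within season.

## Phenotype-level statistics

Broad-sense heritability uses the one-way random model
`y_ij = μ + g_i + e_ij` and the expected-mean-squares estimator:
`σ²e = MS_error`, `σ²G = (MS_geno − MS_error)/n_rep` (harmonic-mean
replication under unbalance, negatives clamped to zero), and
`H² = σ²G / (σ²G + σ²e/n)` on an entry-mean basis over `n` environments.
The method-of-moments path is deliberate: it is exact in balanced data and
has no optimizer state, which makes it the canonical target for tests.
Accession means per season are the analysis unit.

LD decay uses composite (genotype-dosage) r², since phase is not modelled,
over intra-chromosomal pairs; binned means are smoothed by a running
minimum (a reproducible substitute for an unstated-bandwidth local
regression) and the decay distance is the linear interpolation of the
first crossing of the critical r² (default 0.1).

## Mixed-model association scan

The scan fits `y = Wα + xβ + u + ε`, `u ~ N(0, λτ⁻¹K)`,
`ε ~ N(0, τ⁻¹I)`, with `K = X_c X_cᵀ/m` the centered relatedness matrix.
`K` is eigendecomposed once; y, W and each SNP are rotated; the restricted
likelihood is profiled over `log λ ∈ [log 1e−5, log 1e5]` by a bounded
scalar optimizer with an explicit boundary check, and `β = 0` is tested by
a Wald F test on `n − q` denominator degrees of freedom. Per-SNP λ
re-optimization is the default; a `null-lambda` mode reuses the no-SNP
optimum for speed. With `K = I` the machinery collapses exactly to the OLS
F test, which the tests verify to 1e−8, and on small panels the
eigen-rotated path matches a direct (full-covariance, generic-optimizer)
REML implementation to 1e−6 relative in p.

Defaults: MAF ≥ 0.05, per-SNP missingness ≤ 0.1 with mean imputation of
residual missing calls, uniform genome-wide threshold 2.60 × 10⁻⁴. The
optional per-chromosome threshold is `1/m_eff` with
`m_eff = m / (1 + (m−1)·max(0, r̄² − 1/(n−1)))`, `r̄²` the mean pairwise
dosage r² in a 50-SNP sliding neighbourhood; subtracting the `1/(n−1)`
null expectation makes `m_eff = m` for independent SNPs by construction.
This rule is an interpretation — the derivation behind per-chromosome
suggested thresholds is not specified by the data source — and is clearly
marked as such. QTL are formed by single-linkage chaining of significant
SNPs within 5 Mb per chromosome (order-invariant and idempotent, checked
against a transitive-closure oracle); the per-QTL variance share is
reported as the peak single-SNP `β²·var(x)/var(y)` in the interval.
`candidate_gene_scan()` is the same scan restricted to a gene interval.

## Differentiation and selection

Per-SNP Weir–Cockerham (1984) two-population components (a, b, c) give
`θ = a/(a+b+c)`; windows aggregate by ratio of sums
(`Σa / Σ(a+b+c)`, the VCFtools "weighted" convention) in 1-Mb windows
sliding by 100 kb from position 1 — where the source material's prose
("each 100-kb window") and its own tool flags conflict, the flags win;
both are configurable.

`xpclr_lite` is a deliberately simplified composite-likelihood sweep scan:
the original recombination-map drift model is replaced by a physical-
distance kernel because no genetic map is assumed. Under neutrality the
object population's frequency `p₂` drifts around the reference `p₁` with a
truncated-normal density of variance ω (estimated genome-wide as the
median of `(p̂₂−p̂₁)²/(p̂₁(1−p̂₁))` over reference-intermediate SNPs), plus
point masses at 0 and 1 for fixation; the observed allele count is
binomial over that density. Under a sweep of strength `c ∈ (0,1]`, drift
variance at a SNP a normalized distance `d` from the window center is
inflated to `ω / (1 − exp(−d/c))` (distances normalized by the half
window, kernel floored at 1e−3). The score is
`2 · max(0, max_c Σ log-likelihood-ratio)` over the grid
{0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1}; because `c → 0⁺` recovers
neutrality the score is non-negative by construction. The drift integral
uses 48-point Gauss–Legendre quadrature, which a test checks against
adaptive quadrature to 1e−6. Sweeps are called per statistic
independently: the top 5% of defined windows, ties at the cut broken to
the leftmost coordinate.

Haplotypes at a two-SNP candidate site follow the inbred-panel convention:
an accession is Hap1/Hap2 only when homozygous for the defining alleles at
both SNPs; heterozygous, missing or recombinant accessions are `other`,
never phased. Frequencies are reported over all accessions of a stratum
(so Hap1 + Hap2 + other = 1), era trends use the Cochran–Armitage test
over the decade bins pre-1950, 1951–1970, 1971–1990, 1991–2010, post-2010,
and trait contrasts between haplotype groups are Welch two-sided t-tests.

## The synthetic-data generator

The generator exists so every stage can be validated by recovery against a
known truth, and its defaults define the package's reference conditions.

* **Weather**: sinusoid-plus-noise daily means (base 22 °C, amplitude
  4 °C, noise 1.2 °C in the bundled trial) over a 120-day season.
* **Genotypes**: Balding–Nichols — ancestral frequencies uniform on
  (0.05, 0.95), per-subpopulation Beta draws at differentiation `fst_b`
  (default 0.1, 3 subpopulations), binomial dosages; positions uniform on
  wheat-style chromosomes. A separate Markov haplotype-copying generator
  (`simulate_ld_genotypes`) produces LD decaying as
  `r²(d) = exp(−2d/scale)`, giving an analytic r² = 0.1 crossing at
  `scale·log(10)/2` for LD-decay oracles.
* **Senescence**: greenness is logistic in AT with a panel-common
  intercept, `g(AT) = g_min + (1−g_min)·σ(c − r·AT)/σ(c)` with
  `c = r0·midpoint` (defaults r0 = 0.01 per °C·day, midpoint 450 °C·day,
  g_min = 0.15). Anchoring the intercept rather than the midpoint keeps
  curves with different rates from crossing, so a slower rate means
  strictly higher greenness at every AT — the property that makes
  "slower r = stay-green" unambiguous and gives a closed-form RSGS truth.
  The rate is `r0 + Σ effects·dosage + polygenic + seasonal noise`; when a
  heritability target is supplied it is interpreted as the entry-mean H²
  at the generated number of seasons, and the seasonal noise variance is
  derived from it.
* **Scenes**: plots mix fixed canopy and soil endmember spectra linearly
  in greenness (canopy NDVI ≈ 0.90, soil NDVI = 0.20, so the 0.6 mask
  separates them by construction); a configurable fraction of pixels per
  plot is pure soil at plot-specific fixed locations (a physical property
  of the field, constant across flights); the panel region is rendered at
  exactly the panel reflectances; and the returned rasters are digital
  numbers under hidden per-band gains drawn once per season, so the
  calibration step is always exercised non-trivially. Flights follow a
  fixed 5-day cadence in the bundled trial (real campaigns fly every 2–4
  days; date jitter is not modelled).
* **Cohorts**: era labels are resampled without replacement into
  fixed-size bins to plant a favorable-haplotype frequency gradient;
  unachievable targets raise an infeasibility error rather than silently
  truncating.

What the generator does **not** emulate: radiative transfer, BRDF and
sun-angle effects, shadowing, geometric distortion, LD between causal and
background markers in the Balding–Nichols panel, genotype-by-environment
interaction beyond an additive seasonal shift, and heteroskedastic sensor
noise. Passing recovery tests therefore demonstrates internal correctness
of the algorithms under clean conditions, not robustness to every
field-data pathology.

## Numerical choices

* RSS/RSGS identities are exact algebra; tests allow only
  floating-point-rounding slack (1e−13).
* The REML profile is optimized on the log scale with interval
  [1e−5, 1e5] and an explicit endpoint check, since `optimize()` never
  evaluates the boundaries.
* Kinship eigenvalues are clamped at zero; SNP columns that are constant
  or fail MAF/missingness filters are dropped before kinship and scans.
* The xpclr_lite likelihood is floored at 1e−300 before logging;
  quadrature uses 48 nodes.
* Stage ties (two flights equidistant in AT) resolve to the earlier date;
  sweep-score ties at the cut resolve to the leftmost window.
* Windows start on the step grid at position 1 and must fit inside the
  chromosome, so a 3-Mb chromosome with 1-Mb/100-kb windows has exactly
  21.

## Problem sizes used in validation

The test suite and reference scripts run at deliberately compact sizes
chosen to exercise every code path with stable statistics: imaging round
trips at 100 plots × 8 flights; mixed-model oracle comparisons at 20
accessions × 50 SNPs; type-I calibration at 500 × 1000 with a permuted
phenotype; heritability and QTL recovery at 400–500 accessions over 20
seeded replicates; Fst oracles over 1000 random instances; sweep recovery
at 120 accessions × 800 SNPs over 20 replicates. These sizes are the
package's reference conditions; all generators scale to larger panels.

## Known limitations

* The per-chromosome `1/m_eff` threshold rule is one defensible reading of
  an unspecified derivation; the uniform threshold is the default.
* `xpclr_lite` scores are not numerically comparable to genetic-map-based
  XP-CLR scores; only their rankings play the same role.
* Unbalanced heritability designs use the harmonic-mean replication
  approximation; strongly unbalanced trials would warrant a REML variance
  component fit.
* The haplotype machinery assumes an effectively inbred panel;
  heterozygote-rich panels would need phasing, which is out of scope.
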