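---
title: "Texture analysis of the peritumoral zone: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture analysis of the peritumoral zone: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peritex)
```

## The problem and the analysis chain

High-grade gliomas (HGGs) and solitary brain metastases (BMs) are easy
to confuse on contrast-enhanced CT: both can show a necrotic centre, an
enhancing margin and surrounding edema. Their peritumoral zones (PZ)
differ microscopically — glioma PZ is infiltrated by tumor cells,
metastasis PZ is pure vasogenic edema — and the premise of this package
is that the infiltration leaves a measurable statistical signature in
the CT texture of the PZ even though it is invisible to the eye.

`peritex` implements the full chain: ROI definition (seeded region
growing with manual edits), intensity normalization and gray-level
quantization, a 275-parameter texture feature set, two-method feature
reduction, Bonferroni-corrected univariate screening, per-feature ROC
characterization, and a multivariate "enter" prediction model whose
fitted values are themselves ROC-characterized. `pz_study()` runs
stages 3–7 on any subjects-by-features matrix; `run_pipeline()` adds
image-level orchestration.

## Normalization and quantization

Every feature family except the absolute gradient operates on gray
levels `1..Ng` (`Ng = 2^bits`; 6 bits for co-occurrence and run-length
families, 4 bits for the gradient family) obtained by limiting the ROI
dynamic range to `μ ± 3σ` and mapping

```
level(x) = 1 + floor( (clip(x, μ−3σ, μ+3σ) − (μ−3σ)) · (Ng−1) / (6σ) + 0.5 )
```

Numerical choices, all configurable:

* **Half-up rounding** in the mapping; the μ±3σ limitation is standard
  but the exact mapping is not, so it is pinned down explicitly and
  tested (an ROI with μ = 100, σ = 10 maps x = 100 to level 33 at 6
  bits).
* **σ is the population standard deviation** over in-ROI pixels,
  matching the moment definitions of the histogram family.
* **Statistics are ROI-restricted**, not whole-image (the convention of
  the texture software this design follows); a `fixed_window` and a
  `full_range` mode exist for sensitivity analyses.
* A **constant ROI** (σ = 0) maps every pixel to level 1 and raises a
  degeneracy flag instead of erroring, so batch runs proceed and mark
  the subject.
* Out-of-ROI pixels carry `NA`; every feature consults the mask, never
  a sentinel intensity.

Because the mapping is affine-invariant, adding a constant HU offset or
rescaling contrast leaves the level grid — and therefore all quantized
features — unchanged; this is tested property-style.

## Feature families and their numerical conventions

* **Histogram (5)**: population mean/variance, standardized skewness,
  excess kurtosis, and `Perc10` — the smallest level with at least 10%
  of pixels at or below it. The default profile keeps one percentile so
  the family counts 5 and the full set 275; an extended profile adds
  Perc1/50/90/99.
* **Co-occurrence (220)**: symmetric GLCMs at 4 directions (H, V, and
  both diagonals) × distances 1–5; pairs crossing the irregular ROI
  boundary are dropped, not padded. Eleven Haralick statistics per
  matrix; all entropies use the natural logarithm with `0·log 0 = 0`;
  `SumOfSqs` is the variance about the *marginal* mean, per the
  original definition.
* **Run-length (20)**: maximal equal-level runs along the 4 directions,
  truncated at the mask boundary; five statistics normalized by the
  total run count, plus the fraction of pixels in runs. Gray-level
  non-uniformity grows with ROI size by definition — cohort designs
  should keep ROI areas comparable (the synthetic generator does).
* **Gradient (5)**: central differences on the 4-bit level grid, at
  pixels whose 4-neighbourhood is fully in-ROI.
* **Autoregressive (5)**: least squares for the causal model
  `x(s) − m = θ₁x_left + θ₂x_upright + θ₃x_up + θ₄x_upleft + e` on
  demeaned levels; σ is the residual SD. Rank deficiency (constant ROI)
  yields undefined θ with σ = 0. Recovery of a planted θ₁ = 0.5 lattice
  within 3 standard errors is part of the acceptance suite.
* **Wavelet (20)**: orthonormal Haar decomposition of the ROI bounding
  box over 5 dyadic scales. The box is **mean-filled** outside the mask
  (zero-fill would inject spurious edge energy) and mean-padded to a
  multiple of 2⁵; a subband energy averages squared coefficients whose
  support overlaps the mask, tracked by 2×2 OR-pooling across scales.
  Subband letters are row-filter then column-filter, so HL responds to
  horizontal stripes. Scale-1 subbands satisfy Parseval against the
  filled box (tested).

Features that cannot be computed (ROI too small for a neighbourhood or
a deep scale) are `NA` with a recorded reason (`undefined_reasons()`),
and downstream statistics drop them per-feature rather than aborting.

## Feature reduction

The **Fisher coefficient** is the between- to within-class variance
ratio with population class variances; ties in the ranking break
lexicographically so runs are reproducible.

**POE + ACC** is reconstructed as: standardize features; POE(f) is the
minimal empirical misclassification fraction of a single-threshold rule
over both polarities; each greedy step minimizes `POE(f) + mean |r(f,
s)|` over already-selected `s`, the two terms weighted equally (the
method's name read literally). The redundancy penalty has a consequence
worth stating plainly: features that all carry the *same* class signal
correlate with each other through the labels (two d = 2 effect features
correlate at r ≈ 0.5), so after the first pick the method deliberately
prefers uncorrelated features over further copies of the signal. The
package's property tests therefore assert that Fisher recovers all
planted effect features and that POE+ACC's first, error-minimizing pick
is an effect feature — not that POE+ACC hoards all of them, which the
criterion is designed to avoid.

## Screening, ROC, and the prediction model

The univariate screen applies the two-sided Mann–Whitney test to every
pooled feature: exact (full enumeration, via the standard
distribution) when the combined sample is ≤ 16 without ties, otherwise
the normal approximation with tie-corrected variance and continuity
correction. The significance threshold is `α/m` with `m` = pooled
unique features + number of clinical covariates (age and sex, +2 by
default), reproducing the published "divide 0.05 by 19" recipe for 17
pooled features. Note `0.05/19 = 0.00263`, which this package uses
throughout.

A design caveat inherited from the original analysis: testing features
*after* selecting them from a wide candidate pool is anti-conservative
(the selected features have the smallest p-values of the pool), and no
Bonferroni divisor tied to the pooled-list length can repair that. The
package's null calibration therefore measures the screening stage in
the regime where its error rate is well defined — a candidate pool of
the same order as `m` (20 null features against a divisor of ≈ 19) —
where the family-wise error sits at the nominal 5% (tested against the
binomial band over 200 replicates). With hundreds of candidates the
realized family-wise error of select-then-test is substantially higher;
treat the screen as descriptive in that regime.

ROC analysis uses the rank (Mann–Whitney) AUC — identical to
`U/(n₁n₂)`, a tested identity — with DeLong placement variance for the
p-value against 0.5, a binomial-exact (Clopper–Pearson on the combined
sample size) 95% CI for the AUC following the convention of the
clinical statistics software the design mirrors, and Clopper–Pearson
CIs for Se/Sp. The operating point maximizes the Youden index over
observed criterion values, lowest criterion on ties; if a score
discriminates downward it is negated internally, the AUC reported
≥ 0.5, and the criterion printed as `≤c` rather than `>c`.

The multivariate stage is an **ordinary least squares linear
probability model** (outcome 0/1, all predictors entered in one step),
not logistic regression: the coefficient scales and the 0–1
fitted-value criterion of the motivating analysis identify this
estimator. Reported per predictor: coefficient, SE, t-based p, partial
correlation `t/√(t²+df)`, semipartial `t·√((1−R²)/df)`, and
`VIF = 1/(1−R²_j)`; exact collinearity is an error naming the columns,
near-collinearity flags `Inf` rather than silently dropping. The
contradictory published omission rule (significant at p < 0.05 yet
"omit p > 0.01") is implemented as an optional post-hoc flag
(`omit_p`), defaulting to no omission, with both thresholds visible.

## The synthetic cohort

The generator emulates the statistical structure the analysis assumes,
not anatomy. Each subject is an edema-plateau image (8 HU base, 1 HU
i.i.d. noise, 1 mm pixels) with an annular ROI between an
"enhancing-rim" disc and an outer margin (width ≥ 10 px, mirroring the
≥ 10 mm PZ inclusion rule; the annulus geometry is jittered only a few
per cent so size-dependent statistics compare texture, not ROI area).

* **Class A (HGG-like)**: a *granular* field — Gaussian-smoothed noise
  (envelope 1.4 px) modulated by a pixel-scale alternating sign — at
  4 HU, plus Poisson-scattered bright blobs (0.35 cm⁻², radius 2.5 px,
  13 HU) playing the role of infiltration foci. The modulation
  concentrates field energy at the resolution limit; the blobs skew the
  intensity histogram upward.
* **Class B (BM-like)**: a smooth field (correlation length 2.5 px,
  2.8 HU) — longer-range, lower-amplitude, blob-free.

These choices were made for analyzability: the Nyquist modulation is
the only texture that robustly *loses* to a smoothed field in the
doubly high-passed HH subband at scale 2 (any smoothed field carries
less HH content than white noise of equal variance), which is what the
expected direction pattern requires. At these defaults the seven
discriminative families reproduce their expected directions (Perc10,
Contrast, DifVarnc, GLevNonU higher in class A; HH scale-2 and HL
scale-3 wavelet energies higher in class B) in well over 90% of
seeded cohorts at n = 17/19 — an acceptance property.

What the generator does **not** emulate: anatomy, partial-volume and
beam-hardening artifacts, contrast kinetics, scanner noise spectra,
inter-operator segmentation variability, or any relationship between
HU values and real tissue. Passing tests demonstrate that the
*pipeline* behaves as specified on data with known structure; they are
not evidence about clinical discrimination.

Determinism: every subject derives its seed as `rng_seed + index`, so
cohorts are bit-reproducible and resizing a cohort preserves its
prefix.

## Problem sizes used by the test and acceptance suites

Chosen as the smallest sizes that exercise each property clearly:
oracle equivalence on 50 random ≤ 12×12 masks; direction agreement on
100 cohorts of 36 subjects at the default 128×128 geometry; null
calibration on 200 feature-matrix replicates; the blob-amplitude
dose-response on 20-subject cohorts at 64×64 with amplitudes 0/4/10
(a study stopping with no significant features contributes AUC 0.5,
i.e. no discrimination). The acceptance script re-runs a full cohort
study and 40 direction-replicates from its `--seed`.

## Known limitations

* The region-growing rule (intensity tolerance + gradient stop +
  radius cap, 4-connected) is a documented reconstruction of
  "gradient and geometric coordinates" delineation, not a reproduction
  of any specific product; likewise the POE classifier and the legacy
  feature-code aliases (`mazda_aliases()`) are best-effort readings.
* DICOM support is deliberately narrow: single-frame monochrome,
  little-endian, linear rescale.
* 2D only; no shape features (the motivating design used none), no
  Gabor/LBP/fractal families, no cross-validation or external
  validation — the prediction model is evaluated on its training
  cohort, exactly as in the original design, and its apparent accuracy
  should be read accordingly.
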