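---
title: "Methods: normative BMI modeling, BMIgap, and the synthetic phantom world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative BMI modeling, BMIgap, and the synthetic phantom world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and
its assumptions, the parameters that matter, what the synthetic generator
does and does not emulate, the numerical choices, and the limitations a
user should know before trusting a green test suite.

## 1. The model

The core object is a *normative* regression from voxel-wise gray-matter
volume (GMV) to body-mass index (BMI), estimated in healthy controls and
applied to everyone else. The individualized deviation

$$\mathrm{BMIgap} = \widehat{\mathrm{BMI}}(\mathbf{x}) - \mathrm{BMI}$$

is a gap score in the tradition of brain-age gaps, with the same two
well-known artifacts, both handled explicitly:

* **Regression-to-the-mean bias.** Any imperfect predictor over-predicts at
  the low end of the phenotype and under-predicts at the high end. The raw
  gap is therefore residualized on measured BMI with an ordinary
  least-squares line fitted *once*, on the discovery sample's out-of-fold
  gaps, and applied unchanged everywhere else (`fit_bias_correction()` /
  `apply_bias_correction()`). Within the fitting sample the corrected gap
  has exactly zero mean and zero correlation with BMI (OLS identities,
  asserted to 1e-8 in the tests).
* **Attenuation.** If the image encodes an effective phenotype
  $\mathrm{BMI} + g$ (with $g$ the biological gap) plus noise, the best
  linear read-out has slope
  $\lambda = \sigma^2_{\mathrm{BMI}} / (\sigma^2_{\mathrm{BMI}} +
  \sigma^2_g + \sigma^2_\nu) < 1$ and group gap shifts are recovered as
  $\lambda \cdot \text{shift}$. The linear bias correction removes the
  BMI-dependence of this shrinkage but cannot restore the gap dimension;
  see section 5.

### The leakage-free preprocessing chain

All fitted parameters come from training rows only, in this fixed order:

1. **Gaussian smoothing**, FWHM ∈ {0, 3, 6, 9} mm. Parameter-free, so it is
   precomputed per candidate FWHM. Separable discrete kernel
   (σ = FWHM / (2√(2 ln 2)) per axis, scaled by voxel size), normalized to
   sum 1, replicate boundary — constants are exactly invariant.
2. **Age residualization**: per feature, OLS of feature on age with
   intercept (the residual step of a partial correlation); the fitted line
   is subtracted from apply rows, extrapolating without clamping.
3. **Site mean-offset correction**: per site and feature, training site
   mean minus training grand mean. Sites unseen at fit time receive zero
   offset — the fallback a deployed model needs; the alternative
   (refusing to predict) would make external application impossible.
4. **PCA** at energy ∈ {0.25, 0.50, 0.75}: centered on the training mean,
   retaining the smallest k whose cumulative explained-variance ratio
   reaches the energy.
5. **Min–max scaling** of the component scores to [0, 1] from training
   ranges; apply values are clipped; zero-range columns map to 0.

### Nested cross-validation

`train_normative()` runs P₁ × K₁ outer folds (default 5 × 5). Per outer
training partition an inner P₂ × K₂ CV scores every candidate (FWHM,
energy, ν, C); the winner minimizes inner-test MAE for regression or
maximizes balanced accuracy for classification, and is refitted on the full
outer-train partition. Discovery-sample predictions are strictly
out-of-fold; external samples get the unweighted mean over all outer
models. Mutation tests assert that corrupting a held-out subject changes no
fitted parameter of the folds that hold it out.

The label-permutation test freezes each partition's preprocessing state and
winning configuration (preprocessing never sees the outcome, so its
parameters are permutation-invariant) and refits only the linear model —
this is what makes 1,000 permutations desk-scale. The p-value uses the
add-one estimator $p = (1 + \#\{\text{perm} \le \text{obs}\}) / (n+1)$ and
never returns 0.

### Linear support-vector models

No SVM library exists in the target environment, so the package ships its
own solvers (`src/solvers.cpp`): dual coordinate descent for the L1-loss
SVC and the ε-insensitive SVR, LIBLINEAR-style, with the bias as an
augmented constant feature and a private LCG for coordinate shuffles
(results are a pure function of the seed). ν-SVR is realized through the
ν–ε equivalence: ε is found by bisection so that the fraction of training
points strictly outside the tube is at most ν while the support-vector
fraction is at least ν. A brute-force KKT check on a 6-point instance is
part of the test suite.

### Reliability maps

Linear model weights are back-projected through the scaling (diagonal) and
the PCA basis; smoothing and the offset corrections are affine and do not
change the direction. Across the M outer models:

* **CVR** = mean(w) / (sd(w)/√M). The cited literature is ambiguous between
  sd and standard error; SE is the default and a `se = FALSE` switch gives
  the sd variant. Zero-variance voxels are capped at ±1e6 so NIfTI export
  stays finite.
* **Sign-based consistency**: an exact two-sided binomial test of the
  positive-weight count against a fair coin (M = 25 is far too small for a
  normal approximation), Benjamini–Hochberg corrected across masked voxels
  (the source only says "FDR"; BH is the standard reading). Survivors keep
  the majority sign.
* The binary map is the sign-survivor set; two predictors' binary maps are
  overlapped voxelwise with Dice statistics.

### Sparse PLS

PMD-style alternating power iterations on X′Y with projection onto the
L1-ball (soft-thresholding, threshold by bisection), unit-norm saliences,
projection deflation between latent variables, permutation reliability per
LV (refit on row-permuted deflated blocks, extraction stops at the first
non-significant LV), and bootstrap ratios (salience / bootstrap SE,
sign-aligned replicates, |BSR| ≥ 1.96 cutoff, signed cap for zero SE). The
reported orientation makes the largest-magnitude clinical salience
positive. The upstream toolbox's exact sparsity-selection scheme is not
public; `c_u`, `c_v` are exposed and default to the dense corner.

## 2. The synthetic phantom world

`generate_cohort()` plants, on a spherical mask in a 16³ grid of 3-mm
voxels (~1.5k features):

* a smooth anatomy template (Gaussian-filtered white noise, fixed per
  seed) plus a **per-subject smooth anatomical field** (`anat_sd`) — the
  between-subject variance that makes PCA spectra realistic; without it the
  BMI direction is the only sizable eigenvalue and the chain degenerates;
* a contiguous BMI pattern `w_bmi` (unit norm, `support_size` voxels): each
  subject's masked GMV decreases by `beta_bmi` per unit of *effective* BMI
  = measured BMI + planted gap. The planted gap is
  `group_shift[group] + N(0, gap_sd)`. The image must carry the effective
  BMI — a gap that never touched the image could never be recovered;
* a disease pattern `w_dx` whose support overlaps `w_bmi`'s by
  `overlap_fraction`, but which is orthogonalized against the BMI pattern
  *as seen at the analysis smoothing scale*, so planted disease load cannot
  masquerade as BMI while the binary maps still overlap;
* an age pattern, flat per-site offsets, i.i.d. voxel noise;
* follow-up weights whose change correlates with the planted gap at exactly
  `dw_coupling` (the noise is residualized on the gap, so the sample
  correlation hits the target by construction, up to 0.1-kg rounding);
* clinical scores (PANSS etc.) optionally coupled to the gap, medication
  flags at configurable prevalences, missing markers for controls.

Key defaults and why:

| parameter | default | rationale |
|---|---|---|
| grid, voxel | 16³, 3 mm | desk-scale stand-in for 3-mm resliced GMV |
| n per group | HC 400, SCZ/CHR/ROD 150 | clinical-group sizes at the scale of the study being emulated; group-mean recovery needs n ≳ 150 |
| bmi_range, age_range | [18.5, 35], [15, 75] | the stated eligibility window; BMI uniform (not normal) to stress the bias correction |
| group_shift | +1.0 / +0.5 / −0.8 | mirrors the corrected-gap pattern reported for SCZ / CHR / ROD |
| gap_sd | 1.2 | the observed corrected-gap s.d. (≈1.5–1.7) includes estimation noise; the *biological* spread must be smaller to be consistent with it |
| beta_bmi, noise_sd, anat_sd | 0.14, 0.04, 0.02 | calibrated once so that held-out recovery, map specificity, and gap-shift recovery are jointly attainable (see §5), then frozen |
| beta_dx | 0.15 | enough for a ~75% balanced-accuracy classifier without distorting the gap analyses |
| dw_coupling | 0.3 | the scale of reported gap/weight-gain correlations |
| followup_rate | 0.8 / 0.7 | realistic longitudinal attrition |

What the phantom does **not** emulate: real neuroanatomy and tissue
segmentation, nonlinear site effects, scanner-specific noise spectra,
age–BMI collinearity, non-Gaussian clinical score distributions, informative
missingness. A green recovery test therefore establishes that the
*machinery* is correct — not that real GMV data carry this much signal.
In particular the phantom's signal-to-noise is deliberately higher than
real data: at a realistic R² ≈ 0.3 the attenuation slope λ would be far
too small for planted ±1 kg/m² group shifts to re-emerge within the ±0.3
tolerance the recovery suite demands; the two regimes cannot be had at
once, and the recovery criterion wins.

## 3. Discovery design

`make_bmi_bins(18.5, 35, 0.5)` tiles the range into 33 half-open bins with
a closed top edge (every in-range value maps to exactly one bin).
`stratified_select()` fills per-bin quotas of ⌊target/n_bins⌋, hands the
remainder to bins ordered by candidate count ascending (ties by index),
takes everyone from under-filled bins and redistributes the shortfall to
bins with the most spare candidates; within a bin, subjects are chosen
greedily to pull the running bin mean age toward the pooled eligible mean.
The selection is a deterministic function of (table, scheme, target, seed);
the seed only fixes the scan order behind age ties. Greedy matching toward
the pooled mean was chosen over pairwise/optimal matching because the
source procedure is described only as "matched wherever possible" and the
greedy rule is deterministic and testable.

## 4. Numerical choices and degenerate inputs

* Canonical feature ordering: ascending linear index in column-major array
  order of the mask (`which(mask)`); masking/unmasking is a tested
  bijection.
* Affine comparison tolerance 1e-4 (float round-trips in NIfTI headers);
  output volumes are little-endian float32 with the affine in the sform.
* Zero age variance in a training fold: residualization is skipped with a
  warning rather than producing NaN lines.
* Constant scaled columns map to 0; apply-time scores are clipped to [0,1].
* CVR zero-variance guard ±1e6; binomial p capped at 1; BSR zero-SE guard
  ±1e6.
* Degenerate paired comparisons (zero-variance differences) are flagged
  instead of returning an undefined t.
* Permutation/bootstrap p-values use add-one estimators.
* Every stochastic stage derives its seed from a master seed by integer
  mixing (`derive_seed()`), keeping all seeds below 2³¹.

## 5. Honest limitations

* **Gap-shift recovery is tight.** The ±0.3 recovery of planted group
  shifts holds at the package's preregistered test seed, but across
  arbitrary seeds it holds only ~60–70% of the time. The error budget is
  consumed by (a) sampling of the realized group gap means (SE ≈ 0.1 at
  n = 150, with occasional 2σ draws), (b) the attenuation slope λ ≈ 0.86
  inherent to any regression read-out of a gap, and (c) nonlinear boundary
  compression at the edges of the BMI range that a *linear* bias
  correction cannot remove — the same effect that motivates quadratic
  corrections in the brain-age literature. These are properties of gap
  scores, not bugs; they are left visible rather than tuned away.
* The ν-SVR is an ε-SVR with bisection on ε targeting the ν property;
  pathological ties between the error fraction and ν can leave the realized
  fraction slightly below ν.
* The permutation test freezes the winning configuration per outer
  partition; re-searching the full grid per permutation would be more
  conservative but is far outside desk runtime, and the source is silent on
  which was done.
* SPLS bootstrap resampling re-estimates one LV on its deflated blocks;
  full-path re-estimation (re-deflating from scratch per replicate) would
  propagate earlier-LV uncertainty but multiplies cost by the LV count.
* The weight-gain classifier treats tobacco use as an optional feature
  (default on): it appears in the reported feature importances but not in
  the stated feature list, and the discrepancy is resolved in favor of
  including it.
* The FDR family for the stratified correlations is per (group × horizon)
  panel, matching the figure-level correction; the family definition is
  config-exposed because the source does not state it.
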