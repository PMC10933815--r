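---
title: "Decomposing resting-state network amplitude: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing resting-state network amplitude: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsnamp)
```

## The model

An ICA-derived resting-state network (RSN) is summarized per subject by one
timeseries, obtained in stage 1 of dual regression: with `X` the N x T
voxel-by-time data matrix and `G` the N x K matrix of signed group spatial
map weights,

    D = (G'G)^{-1} G' X,

so row `d_k` of `D` is the least-squares combination of all voxel
timeseries weighted by map `g_k`. The **network amplitude** is
`a_k = sd(d_k)`. Because `g_k' X` is a weighted sum of voxel timeseries,
`a_k` mixes two distinct properties of the underlying voxels:

1. **Temporal synchrony** `s_k`: how phase-aligned the strongly weighted
   voxels are (with signs as prescribed by the map — anticorrelated
   sub-regions should anticorrelate). It is computed by re-running the
   spatial regression on temporally normalized data (every voxel z-scored),
   so all voxel-level amplitude information is removed:
   `s_k = sd(d_hat_k)`, `D_hat = (G'G)^{-1} G' X_hat`.
2. **BOLD amplitude** `b_k`: the raw size of the voxelwise fluctuations,
   summarized from the vector `v` of per-voxel timeseries SDs over the
   voxels exceeding the map threshold `|Z| > 3.29` (two-sided p = 1e-3).
   Three variants are provided: the binary-mask mean (default), the
   map-weighted sum `g_k'v / N`, and the root-sum-of-squares
   `sqrt((g_k o g_k)'(v o v))`; on realistic cohorts they rank subjects
   near-identically.

If every voxel had a common SD sigma, then exactly `a_k = sigma * s_k`;
`sigma_identity_check()` verifies this identity on suitable runs. In
general the amplitude is driven by a combination of synchrony and
voxelwise amplitude, and the scientific question is which factor dominates
the intersubject variability. `rsn_decompose()` computes all three measures
for a cohort and is the package's central estimator.

Two conventions worth stating explicitly:

* All SDs use the sample denominator (T - 1). The choice cancels in every
  across-subject correlation.
* The `(G'G)^{-1}` factor is always applied exactly (via QR), although it
  is common to all subjects and cancels from intersubject comparisons.
* `v` is the vector of per-voxel standard deviations, not variances: only
  then does halving every voxel's signal halve each BOLD-amplitude variant,
  which is the defining linearity of an amplitude.
* The mask threshold is a strict inequality, `|g_k(i)| > z`.

## Downstream machinery

**Connectivity.** `partial_correlation()` builds the K x K netmat from the
inverse covariance of the stage-1 timeseries (`C_ij = -P_ij / sqrt(P_ii
P_jj)`), with an optional ridge (as a fraction of the mean variance; the
default is 0 because T is comfortably larger than K here) and a
full-correlation variant behind a flag. `summary_fc()` reduces each
network's row to its absolute / positive / negative means, excluding the
diagonal; empty sign classes are NA rather than 0.

**Clustering.** `amplitude_covariation()` correlates network columns across
subjects; `ward_cluster()` applies Ward linkage (`ward.D2`) to the
Euclidean distances between the rows of that matrix. The exact
dissimilarity was a genuinely open choice; Euclidean-between-rows is the
standard Ward contract and treats each network's whole covariation profile
as its feature vector, while `1 - r` is exposed as an alternative. The
default cut is two clusters, reflecting the sensory/cognitive split such
cohorts exhibit.

**Statistics.** `deconfound()` residualizes on a confound matrix plus
intercept, per column, on complete rows. `impute_missing()` is
soft-shrinkage SVD completion; because a fixed near-zero threshold cannot
make progress from the mean-filled start (the full-rank SVD reconstructs
the matrix exactly), the threshold is annealed geometrically from half the
leading singular value down to the target, warm-starting each stage. The
default target is 10% of the leading singular value; tolerance 1e-6 and at
most 200 inner iterations per stage. Observed entries are never modified.
`compare_dependent_correlations()` implements Dunn & Clark's z with the
backtransformed-average modification of Hittner, May and Silver for two
overlapping dependent correlations — the recommended default in the cocor
family of tests — and is validated in the test suite against a
permutation-of-measure-labels oracle and by a 2000-replicate null
calibration. All p-values are two-sided. `fit_regression()` z-scores every
variable except the 0/1 sex indicator and builds the interaction and
quadratic terms (age x sex, age^2, age^2 x sex) from z-scored age, so
coefficients are comparable across measures and units.

## What the synthetic cohort emulates

Real cohort data of this kind sit behind controlled access, so the package
ships a generator whose planted parameters make every downstream stage
testable. Voxel `i` of network `k` follows

    x_i = sigma_i * ( sqrt(rho_k) sign(g_ki) s_k
                      + sqrt(1 - rho_k) eps_i + noise_sd * eta_i ),

with `s_k` zero-mean unit-sample-SD latent network signals, `rho_k` the
subject's planted synchrony, and `sigma_i` the planted voxel SD scale.
Design choices, and why:

* **Latent signals** are white Gaussian noise low-pass filtered at 0.1 Hz
  (TR 0.735 s): realistic BOLD-like autocorrelation without committing to a
  hemodynamic model. The cutoff is a convention and is exposed
  (`lowpass_hz`, `Inf` gives white signals). A consequence worth knowing:
  at T = 490 the band keeps ~36 positive-frequency bins, so correlation
  estimates carry roughly 1/sqrt(72) of sampling noise.
* **Unit sample SD, not just unit population SD**: the latent signals and
  noises are standardized over the realized run. This removes finite-T
  variance-estimation noise from the planted synchrony scale; with
  population scaling the recovery correlation between planted `rho` and
  estimated synchrony would be attenuated by irreducible SD-estimation
  noise of the band-limited signals.
* **The noise term sits inside the sigma scaling**, so rescaling
  `voxel_sd_range` by c multiplies every voxel timeseries — and hence
  every amplitude measure — by c exactly while leaving temporal synchrony
  untouched. This exact separability is an invariant of the generator and
  is tested at 1e-10.
* **Between-network correlation** is induced by mixing latent factors
  through the Cholesky factor of the target matrix, giving an analytic true
  FC. With `fc_coupling > 0` the subject's latent correlation for networks
  (j, k) is the baseline Schur-multiplied by
  `(1 - c) + c * rho_j rho_k / hi^2`, which stays positive semidefinite by
  the Schur product theorem. This couples connectivity to synchrony — the
  empirical regime such cohorts exhibit, where amplitudes and connectivity
  strength covary — and it is what makes the amplitude-FC association
  analyses recoverable. Defaults: baseline 0.5, coupling 0.8. With
  coupling 0 the baseline is constant and there is, by construction, no
  amplitude-FC covariation beyond noise-attenuation effects, which are
  negligible once ~40 voxels average the idiosyncratic noise away.
* **Two-block structure**: planted synchrony draws share a block-level
  latent (`rho_block_weight`, default 0.8) over a two-block partition of
  the networks (sensory-like / cognitive-like), so covariation clustering
  has a ground-truth partition. Voxel-SD draws instead share a global
  subject-level latent (`sd_global_weight`), so BOLD-amplitude covariation
  deliberately carries no block structure — clustering amplitude or
  synchrony recovers the partition, clustering BOLD amplitude does not.
* **Phenotypes** are linear in the z-scored cluster means of the planted
  synchrony and voxel-SD scales plus confound contributions and unit
  Gaussian noise; missingness is MCAR per column (real-cohort missingness
  is not MCAR; nothing downstream here depends on the mechanism).
  Confounds are standard normal with configurable effects on the
  phenotypes and on the planted synchrony.
* **Geometry is a flat 1-D voxel grid** with contiguous network blocks,
  partial overlap between neighbours, and a configurable fraction of
  negative weights. No downstream computation uses spatial geometry, so
  spatial smoothness is out of scope; NIfTI export reshapes to a 3-D box
  purely for interoperability.

What passing tests on this generator do **not** show: hemodynamic realism,
scanner artifacts, motion, registration/misalignment effects, non-MCAR
missingness, or spatially realistic map shapes. Results on synthetic
cohorts demonstrate that the estimators recover what was planted under the
stated model, not that real data satisfy that model.

## Numerical choices and degenerate inputs

* Spatial regression refuses (near-)singular designs, reporting the
  condition number; the restricted per-network regression of the
  threshold-sweep analysis refuses empty or zero-weight masks.
* Temporal normalization errors on zero-variance voxels, listing them; no
  silent dropping.
* Masks with fewer than two voxels are an error (a one-voxel "network"
  timeseries has no synchrony content).
* The threshold sweep restricts both the map column and the normalized data
  to each network's mask and re-solves the single-column regression per
  network independently; whether other networks' columns should be kept in
  the restricted design is not determined by the problem, and the
  single-column form is the one whose z = 0 limit reproduces the full
  solution when supports are disjoint.
* Ward merges are deterministic given the dissimilarity; `hclust` breaks
  height ties by merge order, which is fixed for fixed input.
* Correlation-based analyses use pairwise-complete deletion; imputation is
  reserved for the regression design, mirroring the usual practice of
  imputing only where a complete design matrix is required.
* Bonferroni families: K x 3 for the across-subject measure-FC tests;
  per predictor across the K networks in the regression suite. Both scopes
  are recorded in the outputs, since the choice of family is a convention.

## Problem sizes

The test suite and the acceptance script work at S = 200 subjects, K = 6
networks, N = 300 voxels, T = 490 timepoints for recovery analyses — the
run length matches the acquisition the model emulates, while the voxel
count and network count are scaled to what the recovery statistics
actually require. Calibration checks use 2000 null replicates (n = 500)
for the dependent-correlation test and 400 replicates for the regression
suite. The end-to-end demo pipeline (K = 4, N = 120, T = 160, S = 30)
completes in a few seconds.

## Known limitations

* Group maps are an input; estimating them (group ICA) is out of scope, as
  are stage-2 dual-regression spatial maps and voxelwise ALFF/fALFF.
* The partial-correlation default is unregularized; for short runs or
  large K set `ridge > 0`.
* The dependent-correlation test assumes bivariate-normal-ish margins; the
  permutation oracle in the tests is the model-free reference.
* Planted synchrony is recovered up to a monotone transform, not in
  absolute units: the measured synchrony depends on map weights and
  network size as well as `rho`.
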