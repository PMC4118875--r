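---
title: "Methods: classifying non-gated LIBS spectra with libsclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying non-gated LIBS spectra with libsclass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(libsclass)
```

## The problem

Conventional LIBS instruments gate the detector to skip the first
microseconds of plasma emission, because that early phase is dominated by
a broad continuum (radiative recombination and Bremsstrahlung) that is
not element-specific. Compact, non-gated CCD spectrometers record the
whole time-integrated signal, so every spectrum is a set of
characteristic atomic lines riding on a large, smooth background. For
*classification* — telling pharmaceutical formulations of similar
elemental composition apart — the continuum is not necessarily a
nuisance: plasmas from different matrices can differ subtly in their
continuum, and a multivariate model can exploit that. `libsclass`
implements the full chain needed to study this question: preprocessing,
continuum removal, outlier screening, PCA, three classifiers (SIMCA,
PLS-DA, a small neural network), and a resampled evaluation protocol,
together with a forward simulator so every stage can be verified without
an instrument.

## Data model and preprocessing

A `spectra_set` holds an `n × p` intensity matrix on one strictly
increasing wavelength grid (nm) with one logical validity mask. The mask
is the single mechanism by which channels are excluded: every statistic
downstream (normalization, baselines, distances, PCA, classification) is
computed on valid channels only, so masked intensities can be arbitrary
without changing any result — a property the test suite asserts
bit-for-bit.

Two preprocessing steps are applied, in this order:

1. **Notch masking.** Channels inside the closed interval
   `notch_center ± notch_width/2` (defaults 532 nm ± 15 nm) are marked
   invalid. The 532 nm excitation laser line saturates non-gated
   detectors over a band of roughly this width, hence the default of a
   30 nm *full* width.
2. **Reference-line normalization.** Each row is divided by its maximum
   valid intensity within `reference_line ± reference_window`
   (656.3 nm ± 2 nm). All the formulations are organic and hydrogen-rich,
   and ambient air contributes hydrogen too, so the Hα Balmer line is
   present in every spectrum and acts as an internal standard against
   shot-to-shot energy fluctuations. The window maximum (peak height, not
   area) is used; the ±2 nm search window absorbs small wavelength
   calibration offsets around Hα. The operation is idempotent and
   scale-invariant, and fails per-row (reporting row indices) if the
   window maximum is not positive.

Whether normalization precedes or follows outlier screening is a genuine
free choice; the pipeline normalizes first, so that outlier detection
operates on the same scale-free representation the classifiers see.

## The forward simulator

`simulate_dataset()` generates labelled spectra as

```
I(λ) = [ continuum(λ) + Σ_l a_l · s_l · G(λ; c_l, fwhm_l) ] · g(λ) + ε(λ)
```

* `G` is a unit-peak Gaussian (amplitude = peak height, a.u.). Stark
  broadening would make real lines Lorentzian/Voigt; with a
  Czerny-Turner instrumental width of ~1 nm the Gaussian core dominates,
  so the simpler profile is used (fwhm defaults 0.8–1.5 nm).
* `continuum(λ) = offset + amplitude · exp(−(λ−center)²/(2·width²))` — a
  deliberately phenomenological stand-in: only smoothness and breadth
  matter for the analyses, not the underlying plasma physics.
* `s_l` is a per-spectrum lognormal multiplier (sd `line_scatter_sd`,
  mean 1) on each line amplitude, modelling pellet inhomogeneity — the
  dominant source of shot-to-shot scatter in pressed-pellet LIBS.
  Default 0.15, i.e. ~15% relative line-intensity scatter.
* `g(λ)` is a fixed-pattern gain vector, `N(1, fixed_pattern_sd²)` drawn
  **once per dataset** (default sd 0.05): CCD pixel response
  non-uniformity is static detector structure, so all spectra of a
  dataset share it.
* `ε(λ)` is Gaussian shot noise with sd `shot_scale · sqrt(I)` (default
  `shot_scale = 0.02`), the usual Poisson approximation at high counts.
* The result is clipped at zero (a CCD reports nonnegative counts).

The default grid is 2068 uniform channels over 350–900 nm, matching a
compact Maya2000-class spectrometer; carbon lines below 350 nm are
therefore outside the simulated range.

`default_formulation_profiles()` defines the four study classes. All
share lines at 479.45 (Cl), 500/567/747 (N), 656.3 (H) and 777/868 nm
(O) — in ambient air every organic pellet exposes H, C, N, O and, for
these formulations, Cl — with class-specific amplitude ratios. Only the
two ciprofloxacin-family classes carry fluorine-tagged lines (placed at
685.6 and 690.2 nm; the *positions* are a simulator choice, only the
presence of fluorine is chemically meaningful). The Cetirizine and
Metformin analogues are the designed **hard pair**: their line amplitudes
and continuum amplitude differ by at most 10% relative, so they are
distinguishable only through subtle intensity ratios — mirroring the
empirically hardest pair of real formulations. The H-line amplitude is
5 a.u. with continuum peak below 5, so the Hα channel is each spectrum's
reference-window maximum.

What the simulator does **not** emulate: wavelength-calibration drift,
detector saturation/nonlinearity, self-absorption of strong lines,
molecular band emission, and matrix effects that couple line ratios to
the continuum shape. Passing tests on simulated data therefore
demonstrate the *algorithms* (calibration, invariances, recovery of
planted structure), not instrument-grade performance on real pellets;
real spectral tables can be loaded through `read_spectra()` and pushed
through the identical pipeline.

`continuum_pair_profiles()` is a purpose-built two-class registry whose
classes differ *only* in continuum amplitude. It operationalizes the
central scientific question: raw-spectrum classification on this registry
succeeds well above chance, and collapses toward chance after continuum
removal — so a drop in accuracy after background removal on real data is
consistent with discriminatory information living in the continuum.

## Continuum removal

`iterative_polyfit_baseline()` is the iterative constrained
("modified") polynomial fit:

1. least-squares polynomial of order `order` (default 6) over valid
   channels, with wavelengths rescaled to [−1, 1] for conditioning;
2. working vector ← `min(working, fit)` — emission peaks are
   progressively excluded from the fit while the smooth background is
   retained;
3. repeat until the maximum relative change of the fitted curve is below
   `tol` (default 1e-4) or `max_iter` (default 100) is reached, in which
   case a warning reports non-convergence and the last iterate is used.

The corrected spectrum is `original − baseline` with negative residuals
clipped to zero by default — the standard reading of the algorithm's
"non-negativity constraint" (constraining the polynomial itself to be
nonnegative is nonstandard and is not done). Order 6 is the conventional
choice for LIBS/Raman continua of this breadth; all parameters are
exposed in `baseline_config()`.

Numerical notes: the working vector is pointwise non-increasing across
iterations by construction, and the converged curve hugs the data from
below up to the least-squares overshoot near peak shoulders, which is
bounded by about 1% of the spectrum scale in practice (a pointwise
`baseline ≤ data` guarantee cannot hold exactly for an unconstrained
least-squares polynomial). Masked channels are excluded from the fit and
their values pass through the correction unchanged.

## Outlier screening

Shots that hit an inhomogeneous spot produce aberrant spectra. The
pipeline clusters each class's spectra (Euclidean distance, Ward
`ward.D2` linkage — the standard pairing for spectra, and one that
yields monotone merge heights) and flags **isolated branches**: after
cutting the tree at `height_factor ×` median merge height (default 3),
clusters of at most `max_branch_size` leaves (default 2) are flagged,
provided at least one larger cluster exists to be isolated *from*.
"Isolated branch" has no canonical quantification, so this rule is a
documented, tunable operationalization; with the defaults it flags
nothing in ≥ 95% of homogeneous-class replicates (low inhomogeneity
scatter) while reliably catching gross planted outliers. Detection runs
per class by default (class means are computed per formulation); a
pooled mode is available. Class-mean spectra after exclusion feed the
class-similarity dendrogram, exportable as a JSON merge list or Newick.

## PCA

`fit_pca()` performs mean-centred PCA over valid channels via the
singular value decomposition. No unit-variance scaling is applied:
spectra are already normalized to Hα, and centring-only is the
chemometric default for spectral data (autoscaling would blow up
noise-only channels). Component signs are fixed (largest-magnitude
loading entry positive) so runs are exactly reproducible. Tests pin the
implementation to a brute-force eigendecomposition of the covariance at
1e-10, plus the rank-1 and isotropic closed-form limits.

## SIMCA

One PCA submodel per class, fitted on that class's training rows only.

* **Rank:** smallest `k_c` whose cumulative variance reaches
  `variance_target` (default 0.95), capped at
  `min(rank_cap = 10, n_c − 2)` so the residual spread remains
  estimable.
* **Distance:** the orthogonal residual distance
  `‖(x − μ_c) − P_c (x − μ_c)‖₂` over valid channels — no score/leverage
  term; thresholding the residual alone is the simplest reading of a
  "3σ unclassification threshold", and the score-distance augmentation
  can be layered on by the user.
* **Degrees-of-freedom correction:** in-sample residual distances are
  shrunk because the submodel mean and `k_c` components are estimated
  from the same rows. Training distances are therefore inflated by
  `sqrt((n_c − 1)/(n_c − 1 − k_c))` — classical SIMCA residual-variance
  bookkeeping — before the acceptance statistics are computed. Without
  this, held-out spectra of a cleanly separable class are unclassified
  at rates of 50% and more at low noise.
* **Threshold:** `mean + sigma_multiplier × sd` of the corrected
  training distances, default multiplier 3.
* **Assignment:** a spectrum accepted by no class is *unclassified*;
  one accepted by several goes to the accepted class with the smallest
  standardized distance `(d − mean)/max(sd, ε)`. This keeps
  misclassification possible in principle while reproducing the observed
  zero-misclassification structure whenever acceptance regions do not
  overlap the wrong class.

Because residual distances are right-skewed (lognormal line scatter), a
3σ band intentionally leaves a small unclassified tail even on perfectly
separable data — a few percent at the default conditions — which is the
soft-classification behaviour SIMCA is chosen for.

## Global classifiers

**PLS-DA.** NIPALS PLS2 of mean-centred spectra against mean-centred
one-hot class indicators, yielding a single global model. Prediction is
the argmax of the predicted class scores (ties break to the
lowest-index class); there is deliberately no rejection option, so its
unclassification rate is structurally zero. The latent-variable count is
chosen by stratified 5-fold cross-validation on the training split
(smallest count within half a held-out misclassification of the best
mean accuracy, capped at 10) unless fixed by the user. The first NIPALS
weight vector is pinned to the SVD of `XᵀY` at 1e-6 in the tests.

**Neural network.** A single hidden layer (default width 8) with softmax
output on *global PCA scores* (components to 99% cumulative variance,
capped at 10), trained with `nnet`; the seed fixes the initial weights,
making training deterministic. The architecture is the smallest design
that is genuinely nonlinear; all hyperparameters are exposed.

## Evaluation protocol

`run_iterations()` repeats, for `n_iterations` (default 100) iterations:
stratified split (per class, `round(n_c × 0.7)` rows to training, round
half up, at least one row on each side; remainder to test), classifier
fit on the training rows, trichotomy rates on the held-out rows. Rates
are averaged *unweighted over classes* (so a printed "Average" row is
the mean of the per-class rows), and each per-class triple sums to 1
exactly. Iteration *i* uses seed `base_seed + i`, so reports are
bit-reproducible.

The `baseline_removed` variant continuum-corrects every spectrum before
any splitting, isolating the effect of background removal.
`compare_reports()` applies a Welch two-sample *t* test (unequal
variances) to the two per-iteration average-correct vectors — the
natural test to run on "mean ± sd over iterations" summaries; when both
vectors are constant the p-value is 1 for equal means and 0 otherwise,
by convention.

## Problem sizes

The test suite runs on coarse grids (126–251 channels) with 5–60 spectra
per class so the full suite completes in well under a minute; the
Monte-Carlo calibration checks use 1000 draws. `scripts/acceptance.R`
uses the full default study conditions — 4 classes × 100 spectra on the
2068-channel grid, 100 evaluation iterations per classifier — and
completes in a few minutes on one CPU.

## Known limitations

* The simulator's noise model is Gaussian throughout (shot noise is a
  Gaussian approximation; no cosmic-ray spikes or saturation).
* The dendrogram outlier rule is an operationalization of an informal
  criterion; on real data the flagged set depends on its two parameters,
  and counts should be reported rather than assumed.
* SIMCA ranks are chosen by a variance target, not cross-validation;
  both the target and a fixed-rank override are exposed.
* XLSX input requires `readxl`; very large spreadsheets are better
  converted to CSV first.
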