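---
title: "Models and methods behind cravereg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cravereg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cravereg)
```

`cravereg` re-implements, as one tested pipeline, the analysis workflow
of a craving-regulation task-fMRI experiment: participants viewed snack
images under three cued cognitive strategies — imagining *positive* or
*negative* future consequences of eating the snack, or focusing on the
*now* — and rated their craving after every trial. The pipeline covers
first-level GLMs, cross-cue searchlight decoding, beta-series network
connectivity, permutation-based group inference, and the behavioral
repeated-measures analysis, all exercised end-to-end on synthetic data
with known ground truth. This vignette documents the models, the
parameters that matter, the design decisions taken where the design was
genuinely open, and what the green test suite does and does not
establish.

## The stated experimental world

The synthetic generator reproduces the design facts of the study it
emulates, which are fixed defaults of `pipeline_config()`:

* 31 subjects; 5 runs per subject; 380 volumes per run at TR = 2 s;
* 36 trials per run, 12 per condition (60 per condition in total);
* each trial: a 2 s strategy cue, a snack image for 6 ± 1 s, a rating
  period of up to 3 s (5-point Likert craving rating), and an
  inter-trial interval of 10 ± 4 s;
* two distinct visual cues per strategy, balanced within run, so that
  decoded strategy information can be dissociated from low-level cue
  identity;
* 36 snack stimuli, 12 bound to each strategy within a subject; the
  binding is rotated cyclically across subjects.

Three timing details are not pinned down by the published description
and are package decisions:

* **Jitter distributions.** Image duration is discrete uniform on
  {5, 6, 7} s and the ITI discrete uniform on {6, …, 14} s. Each run
  draws them as *shuffled balanced multisets* (every value equally
  often), which fixes the per-run totals at 756 s + 4 s lead-in =
  760 s = 380 × 2 s. Free i.i.d. draws would overflow the run roughly
  half the time; the balanced draw keeps the uniform marginals and the
  schedule always fits.
* **Pseudorandomization.** Trial order is a constrained shuffle with at
  most 3 consecutive same-condition trials, preventing condition/drift
  confounding.
* **Snack permutation.** The stimulus-to-strategy assignment rotates
  cyclically over subjects — the simplest scheme that guarantees every
  stimulus set serves every strategy across the group.

The spatial world is a phantom: a 20³ grid of 3 mm voxels by default
(12³ in the calibration simulations; the acquired 64 × 64 × 33 matrix is
available by configuration), with a "brain mask" equal to the grid
interior and an atlas of 116 contiguous parcels standing in for the AAL
parcellation used for network construction. Parcels are consecutive
chunks of a serpentine raster walk, so each is connected and sizes are
equal to within one voxel.

### Planted effects

`effect_spec()` states what there is to find:

* condition-specific mean-signal increases in small cubic regions
  (defaults: regulation amplitude 1, now amplitude 0.5, in units of the
  convolved regressor);
* a **cue-invariant multivoxel pattern** distinguishing positive from
  negative strategy: per-voxel weights drawn once from
  N(0, `pattern_sd`²), entering with sign +1 for positive and −1 for
  negative trials, identically for both cues — exactly the kind of
  information the cross-cue searchlight is designed to detect, and
  `pattern_sd = 0` with `strategy_symmetric = TRUE` (positive and
  negative sharing one region) yields a world with *no* strategy
  information, the null for chance calibration. The symmetric option
  exists because spatially distinct univariate responses are themselves
  decodable — a "null" with separate positive/negative regions is not a
  null for decoding;
* optionally, per-trial amplitude jitter whose across-trial correlation
  between parcels is an exchangeable background (r = 0.2) plus a
  `delta_r` increment on a planted 5-node subnetwork in the positive
  condition only — the target of the network-based statistic;
* stationary AR(1) Gaussian noise (marginal SD `noise_sd = 1`,
  coefficient `ar1 = 0.3`), slow cosine drift, and a constant baseline
  of 100. These are generator parameters, not study facts; they were
  chosen once to give realistic single-trial SNR (trial effects well
  below the noise floor, region effects detectable after averaging) and
  are not tuned against test outcomes.

## First-level model

Condition regressors are boxcars over the combined cue + image epoch
(2 + 6 ± 1 s), convolved with the canonical double-gamma HRF
$h(t) \propto g(t; 6, 1) - g(t; 16, 1)/6$ (gamma densities; peak
rescaled to 1), sampled at frame onsets from a 0.1 s microtime grid.
Three design variants share one nuisance set (rating-period regressor,
ITI regressor, optional six motion regressors, discrete-cosine drifts
below 1/128 Hz — `floor(2·380·2/128) = 11` columns at full length — and
a constant):

* **univariate** — three condition regressors; contrasts
  positive + negative > now, negative > positive, positive > negative;
* **mvpa** — one regressor per strategy × cue combination (4 columns);
  the now condition becomes one further nuisance column. Whether the
  published model treated *now* as a condition or a nuisance is not
  stated; nuisance was chosen so the decoded patterns involve only the
  two regulation strategies;
* **beta_series** — one regressor per regulation trial
  (least-squares-all; the cited beta-series approach does not prescribe
  LSA vs LSS, and LSA is the transparent default at this trial
  spacing), with *now* trials again collapsed to a nuisance column.

Estimation is two-pass: OLS, then a single AR(1) coefficient pooled
over in-mask voxels, exact AR(1) square-root whitening of data and
design, and a re-fit. Pooling (rather than voxel-wise AR estimation)
follows the SPM practice of regularizing autocorrelation estimates and
is far more stable at phantom scale. One numerical point deserves
emphasis: the lag-1 autocorrelation of OLS *residuals* is biased by the
residual projection (expectation −tr(LH)/(n−p) under white noise, with
H the hat matrix and L the lag-1 operator — about −0.075 for the test
designs). `fit_glm()` subtracts this design-dependent null bias before
whitening; without it, whitening white noise with a spuriously negative
coefficient inflated null t-quantiles by ~13%. After correction, white
noise yields ρ̂ ≈ 0, planted ρ = 0.4 is recovered near 0.38, and the
null t-map's 95th percentile matches the theoretical t quantile.

Contrast t-maps use the whitened (X'X)⁻¹ and pooled residual variance;
smoothing is separable Gaussian (σ = FWHM/(2√(2 ln 2)) per axis,
renormalized at edges so constants are preserved), FWHM 8 mm by
default. MVPA runs on *unsmoothed* beta maps; only accuracy maps are
smoothed afterwards, mirroring the native-space-then-normalize order of
the original workflow (spatial normalization itself is out of scope —
synthetic subjects share one grid).

## Cross-cue searchlight decoding

For every in-mask voxel, a sphere of radius 3 voxels (123 lattice
offsets) collects the per-run beta patterns of the four strategy × cue
regressors. A linear support vector classifier with C = 1 — implemented
as a small deterministic SMO solver on the dual problem, since no SVM
package exists in the target environment — is trained on the patterns
of one cue from four runs (4 patterns per class) and tested on the
*other* cue's patterns from the held-out run. Only cue-invariant
strategy information can support above-chance transfer; a pattern that
reverses between cues yields at- or below-chance transfer (verified by
an adversarial test). The published description names one direction
(train cue 1, test cue 2) while referring to all possible combinations;
both cue-role assignments are computed and averaged (symmetry, lower
variance), giving 5 folds × 2 directions = 10 cross-classification
steps whose mean accuracy is assigned to the center voxel. Spheres are
clipped at the mask; centers with fewer than 10 in-mask voxels are
reported missing rather than estimated. Betas enter as-is (no
within-sphere scaling; unspecified in the source and irrelevant to a
linear SVC's decision up to margins).

Empirical chance maps re-run the full decoding under strategy-label
permutations. The exact permutation scheme of the original supplement
is not in the main text; the package flips, per permutation and per run
independently, the positive/negative assignment of both cues together —
the coarsest exchangeable unit that respects the cue structure and the
run-wise estimation.

## Group inference

Second-level tests are one-sample t-tests of subject maps against 0,
against the theoretical 50% chance level, or against the voxel-wise
empirical chance map (both modes exposed). A per-subject covariate
(mean positive − mean negative rating) may be included; the reported
statistic is then the t of the intercept with the covariate centered,
which reduces *exactly* to the plain test when the covariate vanishes.

The original work used random-field-theory peak-level FWE correction.
This package deliberately substitutes **sign-flipping max-statistic
permutation**: under a sign-symmetric null the maximum-t distribution
over the mask (or an ROI, giving small-volume correction for free) is
resampled exactly, needing none of the smoothness assumptions RFT
requires — assumptions a phantom grid would violate anyway. Empirical
family-wise error under the global null measures 0.05 to within
Monte-Carlo error. Supra-threshold clusters use 6-neighbour face
connectivity (conservative; unspecified in the source) and peak tables
report region label, cluster size, peak world coordinates
(voxel size × 0-based index on the phantom grid) and corrected peak p —
the layout of the usual activation tables.

## Beta-series network connectivity

Trial-wise betas are averaged within each of the 116 parcels, grouped
by condition across runs (60 trials per condition), and correlated
(Pearson) to give one 116 × 116 matrix per condition and subject.
Zero-variance parcels yield flagged-missing edges, excluded listwise.

The **network-based statistic** compares the two conditions per edge
with a paired t on Fisher-z-transformed correlations (variance
stabilization; the source is silent on the transform), under random
within-subject condition flips. Edge p-values are pooled symmetric-rank
permutation p-values: the observed and each permuted statistic are
ranked against the other `n_perm` values, so p has resolution
1/`n_perm` and a strict maximum gets p = 0. This keeps the published
link threshold p < 0.001 attainable at 500–1000 permutations (a
+1-corrected p-value could never fall below 1/1001) and makes observed
and permuted supra-threshold graphs exchangeable, so the max-component
null distribution — component statistic: edge count, per the reference
NBS approach — controls FWE exactly; measured ≈ 0.02–0.03 at α = 0.05.
Link-wise FDR applies Benjamini–Hochberg step-up to the *same* edge
p-values and reports the connected components of the rejected set.

## Behavioral analysis

Per-subject condition means of the craving ratings (missing-response
trials dropped — the aggregation rule for missed ratings is not
specified in the source) enter a one-way repeated-measures ANOVA.
Mauchly's W is computed on the orthonormalized contrast covariance with
the standard two-term asymptotic null; when its p < 0.05 (the trigger
is a package decision — the source reports applying the correction "due
to a violation" without naming a criterion) the Huynh–Feldt ε rescales
both degrees of freedom, with ε clipped at 1 per convention. The
implementation agrees with base R's `anova.mlm`/`mauchly.test`
machinery to 8 decimals in the test suite. Two-condition input
degenerates exactly to the paired t (F = t²). Post hocs are dependent
t-tests with the Bonferroni threshold α/3 = 0.0167 (0.017 at 3 dp)
reported alongside raw p-values; the baseline assignment check is the
same RM-ANOVA on pre-experimental ratings, with df (2, 2(n−1)) =
(2, 60) at n = 31.

A caveat the test suite documents explicitly: "corrected p ≥
uncorrected p" holds for Bonferroni unconditionally but for the
Huynh–Feldt df rescaling only in the rejection-relevant region (for
F well below 1, shrinking both df can lower the upper-tail p); the
property is therefore asserted where it is true and decision-relevant.

## Numerical conventions and degenerate inputs

* All exported stochastic operations take an explicit seed, scope it,
  and restore the caller's RNG state; pipeline stages derive child
  seeds deterministically from the one configured seed, so a fixed
  seed reproduces every report bit-identically.
* SVC decision ties (score exactly 0) predict the positive class;
  training is deterministic given input order.
* Permutation p-values for group peaks and NBS components use the
  (1 + b)/(m + 1) convention; NBS *edge* p-values use the pooled-rank
  convention described above, for the stated reason.
* BH step-up uses the standard "reject p₍ᵢ₎ for all i ≤ max{i : p₍ᵢ₎ ≤
  iq/m}" rule.
* Empty event tables parse to empty tables; unknown condition labels,
  non-monotone onsets, rank-deficient designs, empty ROI masks,
  sub-minimum subject counts and non-positive-definite target
  correlation matrices all raise labeled errors rather than producing
  numbers.

## What a green suite establishes — and what it does not

The synthetic world is stationary Gaussian AR(1) noise on a phantom
grid with block-shaped effects. It deliberately omits head motion
(motion regressors are exercised with small synthetic parameters, but
no motion corrupts the data), physiological noise, spatial
normalization error, anatomical structure, and real stimulus
variability. Green tests therefore establish that the *estimators and
tests* are correctly implemented and calibrated — planted amplitudes,
autocorrelations, patterns, rating means and subnetworks are recovered,
and null simulations attain their nominal error rates — not that the
pipeline would reproduce the original study's empirical tables, which
no desk-scale simulation can (and whose data are not deposited). The
acceptance suite encodes exactly this split: printed design facts are
realized exactly; statistical behavior is validated as properties.
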