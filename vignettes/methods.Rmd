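---
title: "Methods: irreversibility, hierarchy, and their inference machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: irreversibility, hierarchy, and their inference machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents what the estimators in `insideout` compute, the
assumptions they rest on, every user-facing default and why it was chosen,
what the synthetic-cohort generator emulates, and the numerical decisions and
limitations a careful user should know about. Code chunks are illustrative and
not evaluated; the test suite and `scripts/acceptance.R` are the executable
record of the package's behaviour.

## 1. Data model and assumptions

The unit of analysis is an `envelope_epochs` container: a cohort member's
recording reduced to an `epochs x regions x samples` array of non-negative
amplitude envelopes at a known sampling rate. The preprocessing helpers
(`bandpass_filter()`, `orthogonalize_symmetric()`, `hilbert_envelope()`,
`epoch_signal()`) produce such containers from broadband multichannel data:

- **Band-pass filtering** uses a forward-backward (zero-phase) Butterworth
  filter via the `signal` package. Zero-phase filtering matters because the
  irreversibility statistic is explicitly sensitive to temporal asymmetry; a
  causal filter would inject an arrow of time of its own.
- **Symmetric orthogonalization** removes zero-lag signal leakage between
  channels with a closed-form symmetric decorrelation (eigendecomposition of
  the channel covariance), under the standard assumption that instantaneous
  cross-channel correlation is dominated by field spread rather than neural
  interaction.
- **Envelopes** are Hilbert magnitudes. The analysis therefore targets slow
  amplitude dynamics of a band-limited carrier, not the carrier phase.
- **Epoching** cuts the continuous envelope into fixed-length epochs; all
  statistics treat epochs as exchangeable realizations and never compute
  across an epoch boundary.

Assumptions: signals are approximately stationary within an epoch; envelopes
are sampled identically across regions; and datasets within a cohort share a
region set.

## 2. The irreversibility statistic

For each epoch, `corr_matrices(X, tau)` computes the forward lagged
cross-correlation matrix `Cf(τ)` with a *truncated-overlap* estimator: the
numerator averages `x_i(t) x_j(t+τ)` products over the `n − τ` overlapping
samples after demeaning each full series, and the denominator uses the
full-series standard deviations. The time-reversed matrix is obtained from the
reversal identity `Cr(τ) = Cf(τ)ᵀ` (verified against an explicit reversal in
the tests to machine precision). Then

- `R(τ) = (Cf − Cr)∘²` element-wise,
- `r(τ)` = mean of the entries of `R(τ)` at or above its 95th percentile
  (`threshold_percentile = 95`).

The percentile-thresholded mean, rather than a plain mean, concentrates the
statistic on the strongly asymmetric pairs and makes it robust to the large
mass of near-symmetric pairs whose `R` entries are dominated by estimation
noise. Per-dataset values (`dataset_irrev()`) average the epoch-level `Cf`
asymmetries across epochs before thresholding, which is lower-variance than
averaging per-epoch `r` values.

A second estimator, `use = "circular"`, computes circular (periodic) lagged
correlations. It exists because the common-phase surrogate (Section 6)
preserves circular cross-correlations *exactly*, giving an algebraic
invariance test; the truncated estimator remains the default because envelope
epochs are not periodic.

### Hierarchy metrics

`region_asymmetry()` reads `R(τ)` per region: the squared outgoing row and
incoming column entries are concatenated, thresholded at the same percentile
within the region's own distribution, and averaged with outgoing survivors
negated. The resulting per-region profile is summarized by
`asymmetry_profile()`:

- **hierarchical coherence** — the mean of `f(A_region)`,
- **hierarchical inhomogeneity** — the standard deviation of `f(A_region)`,

with `f = abs` by default (magnitude of directedness regardless of sign;
`f = identity` is available when net direction matters). Coherence measures
how directed the system is on average; inhomogeneity measures how unevenly
that directedness is distributed — both shrink as asymmetric coupling is
removed.

## 3. Lag selection

`τ` is a free parameter. `irrev_curve()` evaluates `r(τ)` over a lag grid
(default: all positive lags that fit in one epoch; a 2-s epoch at 200 Hz
admits 399). `select_tau_crossval()` chooses `τ` by participant-fold
cross-validation: folds are counter-balanced over the design grid
(`make_folds()`), the training folds pick the lag maximizing the paired
drug-contrast effect size, and the held-out fold contributes an unbiased test
statistic; the final p-value comes from a paired permutation test on the
held-out contrasts. This avoids reporting a lag *and* a p-value selected on
the same data. `cluster_perm_test()` offers the complementary
whole-curve view: cluster-based permutation over contiguous lag runs, with the
cluster-mass null built from sign flips of participant difference curves.

Defaults: `n_folds = 8` (16-participant designs give 16 datasets per fold),
`n_perm = 999` where runtime allows, `alpha = 0.05`.

## 4. Inference contracts

- `paired_permutation()` — exact sign-flip test on paired differences; with
  `n` pairs and fewer than `2^n` requested permutations it samples flips,
  otherwise it enumerates. p-values use the `(1 + exceed) / (n + 1)`
  convention, so they are never zero.
- `rm_anova()` — repeated-measures ANOVA with participant as the error
  stratum, built on `stats::aov` with the formula and data inlined into the
  stored call so that `emmeans` post-hoc contrasts can re-fit it. Inputs are
  validated for balance; single-level factors are rejected.
- `normality_battery()` — D'Agostino K², Jarque–Bera, Shapiro–Wilk,
  Anderson–Darling and Lilliefors checks of the paired differences, since the
  permutation test's exchangeability assumption is weaker than, and preferred
  over, normality-based alternatives when these fail.

## 5. Recurrence dynamics

`sliding_metric()` tracks a metric (e.g. irreversibility) in overlapping
windows (defaults: 1-s windows, 80% overlap, six windows per 2-s epoch);
windows never straddle epoch boundaries. The resulting metric time series is
embedded with standard delay-embedding heuristics — `mi_delay()` (first local
minimum of histogram mutual information, with a documented fallback to the
autocorrelation 1/e time when the MI curve is monotone) and `fnn_dimension()`
(false-nearest-neighbour counts with a distance-inflation factor of 2) — and
converted to a recurrence network by `recurrence_network()`, which selects the
*smallest* ε that makes the recurrence graph connected (binary search over
pairwise distances plus breadth-first connectivity checks). The recurrence
rate at that ε (`metric_recurrence_rate()`) is the dynamical summary: higher
values indicate more recurrent, lower-dimensional metric dynamics. Degenerate
inputs are defined explicitly: a constant series has ε = 0 and recurrence
rate 1.

## 6. Surrogates

`coherent_phase_surrogate()` implements two null models for "same spectra and
cross-spectra, no nonlinear temporal structure":

- `"common_phase"` — one random phase per free frequency added to *all*
  channels, with Hermitian symmetry enforced. This preserves every circular
  auto- and cross-correlation exactly (a property the tests verify to 1e-10),
  so any drop in a statistic under this surrogate isolates structure beyond
  second-order circular correlations.
- `"cholesky_csd"` — draws new realizations from the estimated cross-spectral
  density via an eigenvalue-based complex matrix square root; this randomizes
  relative phases while matching the CSD in expectation.

## 7. Classifier comparison

`build_features()` assembles per-dataset feature vectors for a chosen metric
family and `rf_evaluate()` runs repeated stratified splits of a
random-forest classifier (via `randomForest`), scoring held-out AUROC with
`pROC`. Comparing the AUROC distribution of irreversibility features against
undirected-FC features asks whether the arrow of time carries *discriminative*
information beyond correlation strength; label-shuffled runs calibrate the
chance level. Splits are stratified by participant so no participant
contributes to both sides of a split.

## 8. Spatial null models

Correlating two brain maps inflates false positives when both maps are
spatially smooth. `variogram_surrogates()` builds null maps that match the
empirical variogram of the target map: value permutations are smoothed with
k-nearest-neighbour exponential kernels over a grid of k (3, 5, 8, 13, 21,
34), the k and kernel scale minimizing the variogram mismatch are kept, and
each surrogate is rescaled to the empirical mean and variance.
`spatial_corr_test()` then compares the observed map correlation against this
ensemble. The acceptance suite calibrates this: on independent smooth maps the
variogram-matched null rejects at ≈ the nominal rate while naive permutation
is inflated several-fold.

## 9. The synthetic-cohort generator

Real resting-state pharmacology data cannot ship with the package, so
`make_cohort()` generates cohorts whose ground truth exercises every claim:

- A directed ring of regions (through a random node ordering) carries the
  asymmetric coupling. A mixing parameter κ interpolates between fully
  reciprocated coupling (κ = 0: time-symmetric in expectation) and fully
  one-way coupling (κ = 1), on top of a weak symmetric background (0.3).
- The coupling matrix is shrunk iteratively until the VAR companion spectral
  radius is ≤ 0.95 (autoregressive leak fixed at 0.5), guaranteeing
  stationarity without altering the coupling *pattern*.
- The VAR `x(t) = a·x(t−1) + C·x(t−lag) + η` drives the *amplitude* of 40-Hz
  carriers; Hilbert envelopes of the synthesized signals recover the VAR's
  temporal asymmetry, mirroring the envelope-of-carrier structure of real
  band-limited recordings.
- Per-subject κ is drawn from a truncated normal (defaults mean 0.6, sd 0.1);
  "drug" sessions multiply it by `1 − drug_effect`, so the drug's ground-truth
  action is a reduction of directed asymmetry. Structural seeds are shared
  within a participant across sessions (same anatomy, different state), while
  noise seeds differ per dataset.

Because κ = 0 cohorts are time-symmetric in expectation, they calibrate the
type-I error of the whole pipeline; κ > 0 with a drug effect calibrates
power. Both calibrations are run in the acceptance suite.

## 10. Numerical choices

- All seeded functions save and restore `.Random.seed`, so library calls never
  perturb user RNG state, and every pipeline seed is recorded in the run
  manifest; reruns are bit-identical.
- Lagged correlations use full-series moments in the denominator, which keeps
  `Cf` bounded and exactly transposable under reversal.
- The Eroglu connectivity ε uses a binary search over the sorted unique
  pairwise distances, so the returned ε is always an attained distance.
- p-values use add-one conventions throughout; no test can return p = 0.
- Containers are plain text (TSV epochs + JSON sidecar) for portability; an
  HDF5 reader interface exists but deliberately errors in this build.

## 11. Limitations

- The irreversibility estimator measures *second-order* temporal asymmetry of
  envelopes; processes that are irreversible only in higher moments, or only
  in carrier phase, are invisible to it.
- The truncated-overlap estimator is biased at lags approaching the epoch
  length; the default cross-validated lag selection mitigates but does not
  remove this.
- The hierarchy metrics describe asymmetry of pairwise correlations; they are
  not causal graph estimates and inherit all confounders of correlation-based
  connectivity (unobserved drivers, leakage residuals).
- The generator is a stationary linear VAR with one coupling lag — a
  calibration instrument, not a biophysical model. Effect sizes measured on it
  do not transfer to real data.
- The spatial null assumes smoothness is captured by an isotropic variogram
  over Euclidean centroid distances; geodesic or anisotropic structure is not
  modelled.
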