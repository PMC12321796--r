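---
title: "Oscillation-based brain-age modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillation-based brain-age modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoba)
```

## The problem

Resting EEG power spectra change lawfully over the human lifespan: the
1/f-like aperiodic background flattens with age, the dominant alpha rhythm
accelerates through childhood, and the balance of band powers shifts.
`neoba` turns these regularities into a brain-age estimator: it
parameterizes each channel's spectrum, derives a compact set of
oscillatory features, augments them with a subject-level matrix of
*inter-feature dependencies*, and regresses chronological age with a small
neural network whose predictions are then decomposed back onto the inputs
by layerwise relevance propagation (LRP).  The intended input is a cohort
of cross- or power-spectra on a fixed grid (the package's native grid is
47 dyadic bins, 1.171875–19.140625 Hz at 0.390625 Hz, usually printed as
1.17–19.14 Hz at 0.39 Hz) over the 19-channel 10–20 montage, reduced to 18
channels after average referencing.

## Preprocessing

Cross-spectral matrices are average-referenced per frequency as
`H S H` with `H = I − (1/n)11'`.  `H` is a rank-`n−1` projector, so the
referenced matrices are singular; one electrode (Pz by convention) is
dropped to restore a full-rank set, and channel power spectra are the real
diagonals.  Each subject's log spectra are then centered by their grand
mean over channels and frequencies — equivalently, linear spectra are
divided by their geometric mean.  This removes the arbitrary global gain
(amplifier scaling, skull conductivity) that otherwise dominates
between-subject variance.  The centering formula is the package's own
convention; any global-scale correction that removes a per-subject
multiplicative factor would serve.

All logarithms in the package are natural logs.  The aperiodic exponent is
invariant to that choice; offsets and peak heights scale by `ln 10`
relative to a base-10 convention, which matters only when comparing
absolute offset values across software.

## Outlier screening

Quality control works per WHO-style age group (≤18, 18–45, 45–60, >60
years; half-open bins so every age is assignable).  The flattened,
z-scored spectra (population-SD z-scores) are projected to two dimensions
and each group's robust location and scatter are estimated by the minimum
covariance determinant (MCD); subjects whose squared robust Mahalanobis
distance exceeds the chi-square(2) quantile at 0.975 (7.3778) are flagged.
The package's 2-D embedding is a deterministic principal-component
projection with a fixed sign convention: it is reproducible across
platforms, needs no tuning, and separates the gross amplitude/slope
artifacts this screen is meant to catch.  Nonlinear embeddings can be
substituted upstream — `flag_outliers()` takes any subject × 2 coordinate
matrix.  Groups with fewer than 5 members are skipped, not pooled, and QC
only flags; exclusion is the caller's decision.

## Spectral parameterization

Each channel's log spectrum is modelled additively as an aperiodic
component plus Gaussian peaks,

$$\mathrm{PSD}(F) = L(F) + \sum_n G_n(F), \qquad
  L(F) = b - \log(k + F^{\chi}), \qquad
  G_n(F) = p_n e^{-(F - c_n)^2 / 2 w_n^2},$$

with the knee `k` pinned to zero by default (the analysis range ends at
19 Hz, below where knees usually matter).  Fitting is staged: a two-pass
robust aperiodic fit (bins whose positive residual exceeds the 0.025
quantile of the positively clipped residual are dropped, flattening peaks
out of the fit), iterative peak extraction on the residual (detection
threshold `max(0.05, 2·SD)` log units, bandwidth limits 0.5–12 Hz, at most
6 peaks), a joint least-squares refit of all Gaussians — overlapping pairs
closer than 0.75 summed bandwidths are merged into the stronger one, since
a single broad bump otherwise splits across two seeded Gaussians — an
aperiodic refit on the peak-removed spectrum, and finally, in fixed mode,
a joint polish of all parameters with analytic gradients.  The polish step is what takes
noiseless recovery from ~10⁻² to ~10⁻⁷ accuracy and costs little because
the staged estimates are already close.

Peak-derived (PP) features use the *dominant* (largest-power) peak, with
ties broken toward the lower center frequency.  Channels without a
detected peak get the subject's median PP values over peaked channels (or
the cohort median as a last resort): the dependency regressions downstream
need complete matrices, and median imputation keeps the imputed channels
neutral.

## The 13 oscillatory features

Per electrode: aperiodic exponent and offset (AP); dominant-peak center
frequency, power, bandwidth (PP); four band-power ratios θ/β, δ/θ, δ/α,
θ/α (PR); and four relative powers δ, θ, α, β (RP).  Bands are δ [1,4),
θ [4,8), α [8,12), β [12,20) Hz — half-open so shared edges are counted
once, with β truncated at the grid maximum.  Band sums are taken over
*linear* power (the stored log spectra are exponentiated first): summing
log-powers would break the scale invariance that is the entire point of
ratio and relative-power features.  On the default grid the four bands
cover 8, 10, 10, and 19 bins, so a flat spectrum has RP-δ = 8/47 and
PR-θ/β = 10/19 — handy exact oracles for testing.

Feature relevance to age is summarized by electrode-wise Pearson
correlations and region means over frontal/central/parietal/occipital/
temporal electrode sets.

## Dependency (ODC) matrices via sparse group lasso

For each subject, each feature's 18-electrode profile `x_i` is regressed
on the other twelve:

$$\min_w \tfrac12\|x_i - A w\|_2^2 + \lambda_1 \|w\|_1 +
  \lambda_2 \sum_j z_j \|w_{G_j}\|_2,$$

with the four feature groups (AP/PP/PR/RP; the target's group keeps its
remaining members) and data-driven group weights `z_j` equal to the sum of
absolute correlations between the target and the group's columns.  The 13
coefficient rows form an asymmetric 13 × 12 dependency matrix per subject.
Columns are z-scored across electrodes before each regression — the
features mix units — and no intercept is needed after centering.  Note a
scale subtlety: on the z-score scale the all-zero solution requires
`λ₁ ≥ max|A'x| ≈ d·|r|`, so the conventional grid `λ₁ ∈ {2⁻¹…2⁻¹⁰}`,
`λ₂ ∈ {0…0.9}` (searched by `sgl_grid_search()`, ties resolved toward
smaller penalties) operates in a mildly sparse regime; defaults are
`λ₁ = 2⁻⁶`, `λ₂ = 0.1`.

The solver is FISTA-style accelerated proximal gradient with step `1/L`
(`L` the squared spectral norm of `A`), monotone restart, and the exact
proximal map of the composite penalty (soft-threshold, then per-group norm
shrinkage).  Convergence is declared on relative objective change below
`10⁻⁸`, followed by a plain proximal-gradient polish driven by the KKT
residual — the objective-change test alone stalls near the square root of
machine precision in parameter accuracy.  Both the L1 null condition
(`w = 0` iff `λ₁ ≥ ‖A'x‖∞` at `λ₂ = 0`) and the group-null KKT bound are
exercised in the test suite against an independent coordinate-minimization
oracle.

By default the penalty pair is chosen once on the full cohort (matching
the flat search the method was published with); `sgl_grid_search()` can be
embedded per training fold for a fully nested, unbiased — but ~100× more
expensive — selection.

## Age regression

The regressor is a fully connected 10-10-10-1 network with tanh hidden
units and a linear output, trained by Levenberg–Marquardt on the residual
sum of squares: solve `(J'J + μI)δ = J'e`, accept on improvement
(`μ × 0.1`), otherwise raise `μ` (× 10) and retry.  When parameters
outnumber training rows the identical step is computed in dual form
`δ = J'(JJ' + μI)⁻¹e`, turning a 4,141² solve into an ~350² one.  Inputs
are min-max scaled to [−1, 1] with parameters fit on training rows only;
age is regressed in raw years.  Weights initialize uniformly in
[−0.5, 0.5] scaled by `1/√fan_in` — with 390 inputs feeding 10 tanh units
an unscaled init saturates the first layer and training stalls.  Early
stopping monitors an internal 15% validation split with patience 10
(`max_epochs` 100).

Levenberg–Marquardt on a ~4,000-parameter interpolating network is
run-to-run variable; the cross-validation harness therefore trains a
committee of 3 restarts per fold, averages their predictions, and clips to
the training age range.  `train_lm()` remains the single-network trainer
(with optional best-of-restarts selection on a shared validation split)
for uses that need one weight set, such as relevance analysis.

Model inputs are the flattened OSF block (electrode-major, 18 × 13 = 234),
the flattened ODC block (row-major, 13 × 12 = 156), or their fused
concatenation (390).  Performance is assessed by 10-fold cross-validation
(seeded random partition, fold sizes within one of each other) with MAE,
R², RMSE and MAPE pooled over out-of-fold predictions and 95% CIs over
fold-level values (`mean ± 1.96·SD/√k`).  Linear, SVR, ridge and
random-forest baselines run on identical folds.

## Relevance propagation

LRP starts from an output relevance of 1 (predictions are explained in
proportions, not years) and propagates backward with a signed
decomposition: positive-weight contributions normalized by the positive
part of the pre-activation (plus positive bias part), negative-weight
contributions by the negative part (plus negative bias part), denominators
stabilized by `ε·sign`, `ε = 10⁻⁹`.  The two branch ratios each sum to one
over upstream neurons, so their raw sum would double the relevance at
every layer with both weight signs present; the package therefore
renormalizes the combined contribution per downstream neuron, which makes
the decomposition exactly conserving and reduces to plain proportional
attribution when only the positive branch is active.  The raw two-branch
rule (`renormalize = FALSE`) and an unsigned-bias variant
(`literal_bias = TRUE`) are available for comparison.  Propagation runs to
the input layer by default; `stop_at = 1` reproduces the
first-hidden-layer reading.  Group relevance is pooled by summing by
default (sums preserve totals; `mode = "mean"` averages over members), and
cohort maps are per-subject maps averaged then renormalized to sum to 1.

## Lifespan trajectories

Normative trajectories of each (electrode-averaged) feature are fitted as
penalized cubic B-spline quantile curves on log(age) at the 25/50/75%
levels: pinball loss minimized by asymmetric-weight IRLS with a
second-difference penalty (basis dimension 8; smoothing chosen by 5-fold
CV on the median pinball loss unless fixed), followed by monotone
rearrangement across levels at every evaluation age so quantiles never
cross.  This deliberately replaces a distributional (GAMLSS-type) fit: the
deliverable is three quantile curves, and direct quantile regression
produces them without committing to a response family.  Curves are defined
only within the observed age range and predictions clamp to it.

## The synthetic cohort generator

`make_cohort()` generates log spectra with the statistical structure the
pipeline assumes, so every stage is testable without data access:

* ages from a youth-heavy two-component Beta mixture on 5–97 y;
* aperiodic exponent falling 2.0 → 1.0 and offset 1.5 → 0.5, both linearly
  in log₁₀(age) (subject-level jitter SD 0.08; small channel-level
  jitter), with a smooth anterior–posterior offset gradient;
* an alpha peak (presence 0.95) whose center rises 8 → 10.5 Hz to age 25
  then plateaus, with posteriorly dominant power whose gradient steepens
  with age;
* a latent coupling strength ρ(age), rising 0.1 → 0.9 in log₁₀(age), that
  ties the alpha bandwidth, alpha center-frequency, theta-bump and
  beta-bump electrode profiles (and the exponent–offset profile pair) to
  the alpha-power profile with independent residuals.  Every coupled
  profile keeps an age-flat mean, so this part of the age signal lives in
  the *dependencies between features across electrodes* — exactly the
  structure the ODC regressions expose — and not in any marginal feature;
* i.i.d. Gaussian log-domain noise, SD 0.05 per bin.

The trajectory constants are the package's own choices, set to the
qualitative shapes reported for lifespan EEG (rapid early decline of
aperiodic parameters, childhood alpha acceleration).  What the generator
does *not* emulate: multi-site batch effects, non-Gaussian artifact
structure, heteroscedastic sensor noise, or raw time series.  Passing
tests on this cohort therefore demonstrate that the pipeline recovers the
kinds of structure it is designed for at realistic noise levels — not that
it harmonizes heterogeneous field data.

`make_cross_spectra()` builds Hermitian, PSD-consistent cross-spectra
(`D^{1/2} C D^{1/2}` with a fixed complex correlation structure) to
exercise referencing, and `inject_outliers()` plants gross shift/tilt
artifacts for QC calibration.

## Problem sizes and numerical choices

The test suite runs the full chain on a 400-subject cohort (10-fold CV,
both OSF-only and fused inputs, ten replicate seeds), 100 seeded solver
problems against the coordinate-descent oracle, 200 noisy spectra for
parameter recovery, and a 400-subject QC calibration — sizes chosen so the
whole suite completes in well under half an hour on a single CPU while
keeping Monte-Carlo error small.  Solver tolerances: SGL objective 10⁻⁸
(KKT polish to ~10⁻¹⁰), spectral optimizer `factr` 10²–10³, LM damping
10⁻³–10¹⁰.  Degenerate inputs are contracts, not silent repairs: constant
spectra columns, zero band powers, missing grid cells, and rank-deficient
QC groups all raise errors naming the offending object; the two deliberate
exceptions are PP imputation (documented above) and zero-variance features
in the dependency regressions, which are z-scored to zero with a warning.

## Applying the package to recorded cohorts

`read_spectra()` ingests the TSV long format (`subject_id`, `channel`,
`freq_hz`, `value`, with a companion metadata table); public lifespan
cross-spectra repositories such as the multinational cross-spectra
collection (accession syn26712693) distribute exactly the tensor this
package models, and after export to TSV the full pipeline —
`qc_cohort()`, `neoba_fit(mode = "fused")`, `relevance()`,
`fit_trajectory()` — applies unchanged.  Multi-site harmonization is out
of scope and should precede import.

## Known limitations

* The incremental value of the dependency (ODC) block is bounded by the
  montage: each dependency coefficient is in essence a correlation
  estimated from 18 electrode samples, so its per-pair standard error is
  on the order of `(1 − ρ²)/√15`.  On the default synthetic cohort —
  where the marginal aperiodic features are themselves highly informative
  — the fused input's advantage over OSF-only is within training noise at
  n = 400 (the test suite measures exactly this), even though the ODC
  block alone predicts age well.  Dependency features should help most
  when marginal levels are noisy or confounded but spatial coupling
  structure is preserved.
* Levenberg–Marquardt stores an n × p Jacobian; cohorts beyond ~10⁴
  subjects would need minibatched or first-order training.
* The flat (non-nested) penalty search mirrors the published procedure but
  is optimistically biased; nested selection is available at cost.
* PP features describe only the dominant peak; multi-peak structure enters
  the model only through band powers.
* The PCA-based QC embedding targets gross amplitude/slope artifacts;
  subtle nonlinear outlier geometry may need a nonlinear embedding fed
  into `flag_outliers()`.
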