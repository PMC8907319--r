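---
title: "Wavelength-segment selection for NIR calibration: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelength-segment selection for NIR calibration: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirselect)
```

## The problem

Instant tea is graded by its moisture, caffeine, tea-polyphenol and
tea-polysaccharide content. Wet-chemistry assays for these components are
slow and destructive; near-infrared (NIR) spectroscopy over
10,000–4,000 cm⁻¹ offers a rapid, nondestructive alternative, provided a
multivariate calibration can map absorbance spectra to content. Most of
the NIR axis carries overlapping overtone/combination bands plus
scatter artifacts, so calibrations built on the full spectrum waste
degrees of freedom on uninformative channels. This package implements a
complete calibration workflow in which a binary particle swarm optimizer
(BPSO) searches over contiguous *wavenumber segments*, a repeated-run
frequency consensus stabilizes the selection, and partial least squares
(PLS) or linear support vector regression (SVR) provides the calibration
model, evaluated with the standard six-figure chemometric report.

## Pretreatment

Replicate scans, when present, are averaged first; the averaged spectrum
is the analytical spectrum. Every spectrum $x$ is then transformed by the
standard normal variate (SNV):

$$x' = \frac{x - \bar{x}}{s_x},$$

with $s_x$ the sample standard deviation across wavenumbers (the $n-1$
denominator; `snv_ddof = 0` switches to the population convention). SNV
removes per-spectrum multiplicative gain and additive offset exactly, the
dominant particle-size and path-length artifacts in diffuse-reflectance
NIR of powders. Rows are required to be non-constant; a constant row is a
hard error rather than a silent NaN.

## Segmentation

The $p$ spectral variables are split into $k$ contiguous segments: the
first $k-1$ of width $\lfloor p/k \rfloor$, the last absorbing the
remainder. With the full-resolution grid ($p = 6539$, $k = 21$) this
yields twenty segments of width 311 and one of width 319. One bit per
segment gives a 21-bit search space — small enough for a swarm to cover
well, and segment-level selection keeps the result interpretable as
wavenumber *bands* rather than scattered single channels.

## Calibration models

**PLS** is implemented as single-response NIPALS: latent variables are
extracted by deflation from column-centered data, maximizing covariance
with the response; predictions are affine in the spectrum. No
unit-variance scaling is applied to X (SNV already put spectra on a
common scale). With as many components as the rank bound, NIPALS
reproduces ordinary least squares — that equivalence, and the exactness
of a one-component fit on rank-1 data, are the package's PLS oracles.
The latent-variable count is never fixed a priori: `choose_n_latent()`
minimizes tenfold RMSECV over 1..`max_latent` (default cap 15), breaking
ties toward the smaller count.

**SVR** is linear $\varepsilon$-insensitive support vector regression
with the penalty at its default, $C = 1$, deliberately untuned. The fit
is delegated to `e1071::svm` on standardized columns and a standardized
response ($\varepsilon$ defaults to 0.1 on that scale). The test suite
cross-checks predictions against an independent quadratic-programming
solution of the SVR dual and verifies the KKT conditions.

**Cross-validation.** `tenfold_split()` partitions samples into ten folds
whose sizes differ by at most one (118 samples: eight 12s, two 11s).
RMSECV pools all out-of-fold residuals before taking the root mean
square, so it is the prediction-set RMSEP definition applied to
out-of-fold predictions and is deterministic given the fold assignment.

## BPSO over segment bitmasks

Each particle is a 21-bit mask. Velocities update as

$$v \leftarrow w\,v + c_1 r_1 (p_{best} - x) + c_2 r_2 (g_{best} - x),$$

are clamped to $|v| \le v_{max}$, and positions are resampled bitwise
with set probability $\sigma(v) = 1/(1+e^{-v})$. Defaults follow the
standard configuration for this problem: swarm 20, $c_1 = c_2 = 2$, 100
generations, $v_{max} = 6$ (bounding set probabilities to roughly
0.25 %–99.75 %, which keeps bits mobile), inertia weight 1.0. The phrase
"weight parameter $|V_{max}|$" in informal descriptions of binary PSO
conflates the inertia weight with the velocity clamp; here $v_{max}$ is
the clamp, and the inertia weight is exposed separately. Personal and
global bests update only on *strict* improvement, which makes runs
deterministic given their seed and the global-best curve non-increasing
by construction. The all-zero mask is assigned fitness $+\infty$, so an
empty wavelength set can never win.

## Consensus selection

A single wrapper-selection run is a local, noisy optimum. The pipeline
therefore runs `n_runs` independent BPSO runs (default 100; the light
profile uses 20) and counts, per segment, how many runs ended with that
bit set. A segment is selected when its count strictly exceeds the
threshold (default 50 of 100 — a strict majority; the light profile uses
10 of 20). Each run draws its own inner tenfold assignment, so a segment
that reduces RMSECV only under one particular split does not accumulate
counts. The final model is refit on the selected variables, with the PLS
latent count re-chosen on that subset.

**Why the latent count must be re-selected per mask.** During
development we first fixed the fitness's latent count at the value chosen
on the full spectrum. That quietly destroys selection specificity: a
count tuned to ~650 variables overfits a 3-segment mask, and appending
*uninformative* segments then lowers RMSECV by acting as incidental
regularizers. The fitness therefore evaluates every truncation
1..`max_latent` (all truncations come from a single NIPALS pass per fold,
implemented in compiled code) and scores the mask by its best truncation.

**What consensus can and cannot filter.** With 118 samples and ~650
channels, a few noise channels will correlate with the response at
$|r| \approx 0.2$ by chance *in the dataset itself*. Such segments lower
RMSECV under every fold assignment, so an RMSECV-minimizing wrapper
selects them no matter how many runs vote — consensus damps split-level
noise and optimizer noise, not finite-sample coincidence. In simulations
the procedure reliably recovers every truly informative segment
(sensitivity), while typically admitting several spuriously helpful ones
(imperfect specificity). Stability-selection or bootstrap variants would
address this but are out of scope. Selected bands should be read as
"sufficient for prediction", not as a certificate of chemical relevance.

## Evaluation report

For one calibration/prediction split the report carries six figures:
$R_c$ and RMSEC from the calibration set, $R_p$, RMSEP, SEP and Bias from
the prediction set, with

$$\mathrm{RMSEP} = \sqrt{\tfrac1n \sum e_i^2},\quad
  \mathrm{Bias} = \bar e,\quad
  \mathrm{SEP} = \sqrt{\tfrac1{n-1} \sum (e_i - \bar e)^2},\quad
  e_i = \hat y_i - y_i.$$

These denominators make the identity
$\mathrm{RMSEP}^2 = \mathrm{SEP}^2 (n-1)/n + \mathrm{Bias}^2$ exact; it
is asserted on every emitted report. $R_c/R_p$ are plain Pearson
correlations between predicted and measured values. Bias is
predicted-minus-reference by fixed convention (negative = model
under-predicts); the convention is not configurable so reports stay
comparable. The outer evaluation holds out one designated fold of a
seeded tenfold split as the prediction set and calibrates on the other
nine, mirroring the practice of drawing the prediction set by tenfold
cross-validation.

## Synthetic data generator

The 118-sample instant-tea dataset this workflow targets is not publicly
deposited, so the package ships a generator that emulates its statistical
structure with known ground truth:

* **Concentrations** are drawn uniformly within the published composition
  ranges (moisture 3.76–6.29 %, caffeine 0.48–2.80 %, tea polyphenols
  18.70–22.40 %, tea polysaccharides 18.00–24.50 %). Uniform is the
  least-assumptive distribution reproducing the published min/max; a
  truncated-normal option matching the published means/sds is available
  (`concentration_dist = "truncnorm"`).
* **Pure-component spectra** are sums of Gaussian bands (the standard
  idealization; widths default to tens of cm⁻¹) whose centers lie inside
  each component's characteristic wavenumber regions — e.g. moisture
  bands inside 6694–7293 and 7892–8193 cm⁻¹, caffeine inside 4000–4894
  and 6994–7293 cm⁻¹. Polyphenol and polysaccharide bands deliberately
  share regions with each other and with moisture, because the
  characteristic regions of those components genuinely overlap; their
  per-percent amplitudes are also smaller. Band support (±2.5σ) for the
  well-separated components is placed so it does not merely graze a
  segment boundary: a segment "planted" by a 3-variable band tail would
  be ground truth in name only.
* **A fixed background spectrum** (broad overlapping bands plus a gentle
  slope, the non-varying tea matrix) anchors the absolute absorbance
  scale. This is not cosmetic: without it, SNV's per-spectrum
  normalization leaves only concentration *ratios* identifiable, and no
  calibration could recover absolute contents.
* **Distortions**: per-sample multiplicative gain (default U(0.9, 1.1))
  and additive offset (U(−0.05, 0.05)) — exactly the artifacts SNV
  removes, verified end-to-end — plus a random degree-≤2 baseline
  (amplitude 0.01) that SNV only partially removes, and iid Gaussian
  noise (default sd 0.002 absorbance units, a realistic FT-NIR noise
  floor that leaves clear margin for segment recovery; config-exposed).

The generator does **not** model instrument line-shape, detector
nonlinearity, replicate-scan noise structure, or chemical interactions
violating Beer–Lambert additivity. Passing recovery tests therefore
demonstrates that the selection-and-calibration machinery works under
controlled, favorable conditions; it does not certify performance on
real tea spectra, where prediction correlations will be lower.

## Problem sizes and profiles

The full-scale profile (`profile = "full"`) runs 100 consensus runs
of 100 generations on the 6539-variable grid. Routine validation uses
the light profile (`profile = "ci"`): a 654-variable grid (same 21
segments, widths 31/34), 20 consensus runs of 30 generations, threshold
10 — the same strict-majority rule at one-fifth the vote count. All
reported experiments in the test suite and the acceptance script use the
light profile; the pipeline's cost is dominated by the ~10⁴ memoized
fitness evaluations per consensus, each a tenfold PLS cross-validation.

## Numerical and degenerate-input choices

* NIPALS stops extracting components when the weight or score norm falls
  below 1e-14 (exhausted X); deeper truncations reuse the last
  extractable one.
* Fold assignment requires `n_samples >= n_folds >= 2`; latent counts are
  capped at `min(n_train − 1, n_vars)`.
* A constant response is an error for PLS; for SVR it yields a constant
  model (inside any tube) rather than an error, since it can arise in
  degenerate folds.
* Zero-variance columns are dropped from the SVR standardization and fit.
* Wavenumber grids are accepted ascending or descending and normalized to
  descending; grid equality across files is judged at 1e-6 cm⁻¹.
* All randomness (fold draws, swarm initialization, per-run streams,
  simulation) derives from user-supplied integer seeds; per-run streams
  use a fixed integer recurrence so the 100 consensus runs are
  independent and reproducible, and the global RNG state is always
  restored.

## Known limitations

* Segment count 21 and the remainder-to-last-segment rule are fixed
  conventions of this workflow; other interval-selection layouts (equal
  remainder spreading, overlapping windows) are not implemented.
* Only SNV pretreatment is provided — no MSC, derivatives, or detrending.
* SVR hyperparameters beyond `C` and `epsilon` are not searched, by
  design.
* Wrapper selection by RMSECV overfits its own criterion at modest sample
  sizes (see consensus discussion above); selected segments beyond the
  known-informative ones should be expected.
* The evaluation's single held-out fold gives an honest but
  high-variance estimate of prediction error; the full 10-rotation
  pooled alternative is available via `pred_fold` iteration by the user.
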