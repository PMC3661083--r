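---
title: "Directed coupling by the extrinsic-to-intrinsic power ratio: model, estimation and design choices"
author: "eipr package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed coupling by the extrinsic-to-intrinsic power ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eipr)
```

## The model

Within one analysis window of $N_\mathrm{win} = T_\mathrm{win} f_s$
samples the $K$-channel signal is assumed zero-mean and stationary and
is modelled as a stable vector autoregression of order $p$:

$$x[n] = \sum_{j=1}^{p} A[j]\, x[n-j] + \varepsilon[n],$$

with white innovations of regular covariance $\Sigma_\varepsilon$.
Stability means the companion matrix of the coefficient stack has
spectral radius below one; every simulation and analytic routine in the
package checks this and reports the radius when it fails. The model is
estimated equation-by-equation: target channel $k$ is regressed on lags
$1..p$ of itself and of the channels in its *extrinsic channel set*
$L_k$, by ordinary least squares over rows $n = p+1..N_\mathrm{win}$.

Two estimation conventions deserve mention because the literature is
silent on them and they affect third decimals:

* **Conditional OLS, no padding.** The first $p$ samples of a window
  serve only as regressors; no pre-sample values are invented. The
  regression therefore has $N_\mathrm{win} - p$ rows, and the residual
  variance is normalized by that row count.
* **Per-window mean subtraction.** The model assumes zero-mean
  channels; recorded biosignals are not. Every fit subtracts the
  per-channel window mean first, unconditionally.

The normal equations are solved through a LAPACK QR factorization; the
contract is the OLS minimizer, not a particular factorization. Designs
whose (implied) normal-equation matrix has condition number above
$10^{12}$ are rejected with a pointer to channel-set reduction, which is
the situation the selection algorithm exists to avoid.

## Channel selection

With dozens of strongly correlated ECoG channels the full regression is
ill-conditioned, so each target's extrinsic set is built greedily
(`selectChannels()`): starting from $L_k = \emptyset$, every remaining
channel is scored by

$$\mathrm{BIC}(L_k) = \ln\!\big(S_\mathrm{err}/n_\mathrm{rows}\big)
  + \frac{M \ln N_\mathrm{win}}{N_\mathrm{win}},
  \qquad M = (|L_k| + 1)\,p,$$

and the minimizer is added as long as it strictly decreases the
criterion. Three design points:

* **Mean squared residual inside the logarithm.** Whether the residual
  sum of squares is normalized before taking the log does not change
  the argmin (the shift $\ln n_\mathrm{rows}$ is common to all
  candidate sets of a step), but only the normalized form puts the
  criterion on the scale of a log residual variance, which is how the
  published stepwise tables for the benchmark system read (the
  intrinsic-only criterion of the autonomous channel sits near 0, i.e.
  at $\ln \hat\sigma^2 \approx 0$ for unit innovations, plus the
  penalty). The unnormalized form would sit near $\ln N \approx 9.5$.
* **Stopping on the full criterion.** The search stops when no
  candidate strictly decreases the penalized criterion as a whole
  (penalty included). A reading in which only part of the expression
  drives the stop would never stop on noise alone.
* **Ties.** Exact BIC ties are broken toward the lowest channel index;
  candidate evaluations are done in increasing index order, so the
  first minimum wins. This makes runs bit-reproducible.

`maxSetSize` caps the search for very large $K$; the default ($K-1$) is
no cap.

## EIPR and its estimation

The partial contribution of source $l$ to target $k$,
$\mu_{k,l}[n] = \sum_j \hat A_{k,l}[j] x_l[n-j]$, decomposes the fitted
equation exactly: intrinsic plus extrinsic contributions plus residual
reproduce the demeaned target. Coupling is quantified by

$$\eta^2_{k,l} = \frac{V\{\mu_{k,l}\}}{V\{\mu_{k,k}\}}.$$

The diagonal is identically 1 and is set so exactly; sources outside
$L_k$ have all-zero coefficients and get exactly 0. The denominator is
assumed bounded away from zero; the implementation enforces a floor of
$10^{-12}$ times the channel variance and raises an error below it.

Two estimators of $V\{\mu_{k,l}\}$ are provided (`partialPower()`):
the default is the empirical variance of the realized $\mu$ series
(population $1/n$ convention, matching the expectation definition); the
alternative plugs the fitted coefficients and the sample
autocovariance of the source into the defining quadratic form
$\sum_{j,j'} \hat A_{k,l}[j]\, \hat r_{x_l}[j-j']\, \hat A_{k,l}[j']$.
They agree to within a couple of percent at benchmark sample sizes and
converge to the same population quantity; which one produced the
published table is not stated, and the tolerance of the reproduction
covers the gap.

### Analytic oracle

For a known model the package computes population quantities exactly
(`stationaryAutocov()`, `truePartialPower()`, `trueEipr()`): the
stationary covariance solves the companion-form discrete Lyapunov
equation (via the Kronecker-vectorized linear system, exact to machine
precision, no spectral quadrature error), higher lags follow the
Yule–Walker recursion, and the partial powers evaluate the quadratic
form above with true coefficients. This is the yardstick the estimators
are tested against.

### Spectral identities

EIPR has an equivalent frequency-domain form through the spectral
density of the partial contribution,
$S_{\mu_{k,l}}(f) = |A_{k,l}(f)|^2 S_{x_l}(f)$, whose integral over the
full band returns $V\{\mu_{k,l}\}$; PDC can be rewritten through the
same densities. `spectralCrossCheck()` verifies all three identities
against the time-domain/Lyapunov values by trapezoidal quadrature on a
uniform grid over $[0, 0.5]$ (doubled for the negative half-axis). One
notational subtlety: the transfer matrix is
$\tilde A(f) = I - A(f)$ with $A(f) = \sum_j A[j] e^{-2\pi i f j}$, and
off-diagonal entries of $\tilde A$ and $-A(f)$ coincide, so either
yields the same off-diagonal moduli; the *intrinsic* (diagonal) filter
is $A_{k,k}(f)$, not $\tilde A_{k,k}(f)$, and the implementation uses
exactly that. At 4096 grid points the quadrature agrees with the
Lyapunov oracle to better than $10^{-3}$ relative (in practice to
machine precision, since the integrands are smooth).

## Surrogate significance

No exact finite-sample distribution of estimated EIPR is available, so
per-pair thresholds come from surrogate data: $N$ copies of the window
(default 100) in which each channel is independently resampled,
destroying inter-channel alignment while keeping marginal structure,
and the one-sided rule

$$\eta^2_{k,l} > \overline{\tilde\eta^2_{k,l}}
  + t^{*}\,\hat\sigma(\tilde\eta^2_{k,l})/\sqrt{N},
  \qquad t^{*} = -t_{N-1;\alpha} \approx 2.3646
  \ (N = 100,\ \alpha = 0.01).$$

Three resampling transforms are implemented; the cited leave-one-out
resampling is not described in its source in enough detail to
reproduce, so the default is the package's own reading of it:

* **`loom`** (default): the window is cut into $N$ equal segments and
  each channel independently drops one randomly chosen segment. This
  desynchronizes channel pairs over a random third of the window on
  average while leaving two thirds aligned, and it reproduces the
  magnitude pattern of the published surrogate thresholds on the
  benchmark system across all four decades (from $\sim 10^{-4}$ for
  the autonomous target's pairs up to $\sim 0.25$ for the strongest
  coupling) — strong evidence that this is what the original
  procedure's thresholds reflect.
* **`circular_shift`**: each channel is rotated by an independent
  uniform offset in $[N/8, 7N/8]$. This preserves marginal
  autocorrelation exactly and destroys cross-alignment completely; it
  yields much smaller thresholds for truly coupled pairs.
* **`block_permute`**: blocks are permuted independently per channel.

Surrogates reuse the extrinsic sets of the original analysis by
default (`reselectOnSurrogates = FALSE`): the null being tested is the
absence of coupling *given* the fitted regression structure, and
re-running selection under the null only inflates surrogate variance.
A single master seed derives one stream per surrogate, so results are
reproducible and independent of evaluation order.

### A calibration caveat, documented deliberately

The threshold above bounds the surrogate *mean* (its $\sqrt{N}$ term is
the standard error of that mean), not an upper quantile of the
surrogate distribution. When the observed statistic is exchangeable
with the surrogate replicates — which is exactly the case for a
non-causal pair whose regressors are uncorrelated with the target's
past — a single draw exceeds such a bound roughly a third of the time,
regardless of $N$. On the benchmark system with selection *disabled*
this is measurable: pairs into the autonomous channel (whose other
regressors correlate with its past in the original data but not in the
surrogates) exceed their thresholds in 30–60% of independent
realizations, for every resampling transform tried. The published
single-realization table happens to sit below its thresholds; that
outcome is not stable across seeds and the package does not pretend
otherwise.

In the method's intended operating mode, however — channel selection
first, thresholds on the selected regression — the problem disappears:
non-causal pairs are almost never selected (the BIC penalty sees to
it), unselected pairs have EIPR exactly 0 against a degenerate
zero-mean surrogate null and are never flagged, and the empirical
pairwise false-positive rate under a fully independent white-noise null
is below 1% at $\alpha = 0.01$ (0/1020 pair-tests in the shipped
calibration check). All pipeline defaults therefore use selection, and
the acceptance checks assess non-causality through the method as
deployed, while the published non-causal example pair is additionally
checked under the selection-free protocol, where it does hold robustly.

No correction for testing all $K(K-1)$ pairs is applied — the original
procedure applies none, and adding one silently would change the
reported operating characteristics.

## Pipeline

`preprocessRecording()` applies the standard conditioning chain for
clinical recordings sampled at 256 Hz: a second-order notch (RBJ
biquad, quality factor 35 — the published chain names only the 50 Hz
cut-off, the filter shape is a package choice) and an 8th-order
Butterworth low-pass at 64 Hz, both forward–backward for zero phase,
then integer-factor decimation to 128 Hz. Non-integer decimation
factors are refused with advice rather than silently resampled.

`analyzeCoupling()` slides non-overlapping 4 s windows (defaults:
$p = 7$, which accommodates a spectrum with about three peaks plus slow
components at 128 Hz) and emits per window the EIPR matrix, thresholds,
and a directed graph. Windows with singular fits are skipped with a
warning, not fatal — clinical recordings contain flat and artifactual
channels. Two edge rules are provided because the published rendering
("an arrow when the value exceeds a threshold") is not quantified:
`significant` draws every threshold-exceeding pair, `top_fraction`
additionally keeps only the strongest fraction (default 0.1) of them,
mirroring a representation restricted to the highest coupling values.
Both are labelled interpretations, deterministic including tie-breaks.

## Synthetic data

Two generators define the test conditions:

* `winterhalderModel()` returns the published 4-channel VAR(5)
  benchmark with identity innovation covariance; 100 s at 128 Hz
  (12,800 samples, one window) is the protocol used throughout the
  tests. `simulateVar()` draws Gaussian innovations — the source only
  says "white noise", but the OLS theory and the Student-quantile test
  implicitly assume light tails; a pluggable sampler is exposed for
  anything else. A burn-in of 1000 samples is discarded: companion
  spectral radii here are at most ~0.95, so transients decay well
  below noise within that span.
* `synthEcog()` emulates a focal onset: independent stable AR(2)
  channels before onset; after onset the designated focus channel
  switches to a resonant AR(2) oscillation (default 8 Hz, pole radius
  0.95) and drives a configurable neighbor set with a lagged gain
  (default lag 2 samples, gain 0.5). The defaults were chosen once to
  give a post-onset coupling that a 4 s window at 128 Hz detects
  reliably without being trivial; channel count, onset sample and all
  gains are arguments.

What these fixtures do *not* emulate — and what passing tests therefore
do not certify for clinical data: nonstationarity inside a window,
non-Gaussian and nonlinear neural dynamics, spike–wave complexes,
volume conduction/common reference effects, artifacts and flat
channels. The fixtures are linear-stochastic by design; they validate
the estimator, the selection, the thresholds and the plumbing, not
neurophysiology.

## Numerical choices, degenerate inputs, limitations

* Frequency grids are uniform on $[0, 0.5]$ normalized; 512 points for
  PDC by default, 4096 for quadrature cross-checks.
* Zero surrogate variance (typical for unselected pairs, whose
  surrogate EIPR is identically 0) makes the threshold degenerate at
  the surrogate mean; exceedance is strict, so such pairs are never
  significant. A message is available behind
  `options(eipr.verbose = TRUE)`.
* Problem sizes in the shipped tests: 20 independent 12,800-sample
  realizations for the benchmark reproduction, 100 for the
  channel-selection recovery, 1020 pair-tests for null calibration, 20
  fixture runs for the pipeline check — sizes at which the
  Monte-Carlo error is comfortably inside the asserted tolerances.
* The lag order is global and fixed per analysis; variable-order and
  penalized (lasso-type) selection are out of scope, as are DTF
  variants, generalized/information PDC, PDC confidence bands, and any
  seizure-onset detection (onset times are inputs).
* EIPR is not normalized to $[0, 1]$; values are comparable within a
  system but not across systems with different intrinsic dynamics.
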