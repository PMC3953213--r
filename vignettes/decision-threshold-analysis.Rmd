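---
title: "Modelling decision thresholds: drift diffusion, bistable switch units, and the lateralized readiness potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling decision thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lrpddm)
```

# The scientific problem

In two-alternative forced-choice tasks, sequential-sampling accounts hold
that noisy evidence is accumulated until it reaches a decision threshold,
at which point the corresponding response is emitted. Most of the
neuroscience of this process has focused on the *accumulation* stage; the
*commitment* stage — how a graded evidence signal is converted into an
all-or-none motor command — is usually treated as an abstract step
function. This package implements, on fully synthetic data with known
ground truth, an analysis chain built around a concrete neural proposal
for that step: threshold crossing as the up-state transition of a bistable
cortical population, observable in humans as the lateralized readiness
potential (LRP), the signed C3/C4 difference wave over motor cortex.

The package has five parts: a pure drift-diffusion model (DDM) engine, a
three-layer network model whose middle layer implements the threshold, an
LRP measurement pipeline, a synthetic behavioral/EEG generator, and the
cross-subject statistics that link LRP measures to DDM parameters.

# The pure DDM engine

Evidence follows \(dX = v\,dt + s\,dW\) between absorbing boundaries at
\(0\) and \(a\), starting from \(z \in (0, a)\); observed RT is the
first-passage time plus a non-decision time \(t_0\). The noise
coefficient is fixed at \(s = 0.1\) (the conventional scaling), so \(v\),
\(a\), \(z\), \(t_0\) are identifiable. An unbiased starting point is
\(z = a/2\). Closed forms used throughout:

- choice probability
  \(P(\mathrm{upper}) = (1 - e^{-2vz/s^2}) / (1 - e^{-2va/s^2})\),
  reducing to \(1/(1 + e^{-va/s^2})\) for \(z = a/2\), and \(z/a\) in the
  driftless limit;
- mean decision time \((a\,P(\mathrm{upper}) - z)/v\), with limit
  \(z(a - z)/s^2\), equal to \((a/2v)\tanh(va/2s^2)\) when unbiased.

First-passage *densities* use the classical series solution with an
adaptive switch between the small-time and large-time expansions: for
each time point the expansion requiring fewer terms at truncation error
\(10^{-10}\) is evaluated. The defective *CDF* (which the fit objective
needs at quantile edges) uses the large-time series for the tail mass
with an adaptively bounded term count; both are validated in the tests
against long fixed-length brute-force sums and against Monte-Carlo
simulation.

## Trial simulation

Paths are integrated by Euler–Maruyama in compiled code at
`dt = 0.1` ms (configurable up to 1 ms), with a 30 s non-termination
guard; guarded trials are dropped with a warning. Discretization causes a
small positive bias in mean RT (crossings are detected at step ends and
within-step excursions are missed, effectively widening the boundaries by
about \(0.58\,s\sqrt{dt}\)); at the default step this is below 1 ms and
the tests allow 2 ms of absolute slack on mean-RT comparisons. Halving or
doubling `dt` moves simulated accuracy by far less than one Monte-Carlo
standard error at the trial counts used.

## Fitting

The fit objective is a quantile-binned multinomial likelihood
(QMPE-style): each condition-by-choice RT distribution is binned at its
observed 0.1/0.3/0.5/0.7/0.9 quantiles, and the bin counts are scored
against the bin probabilities implied by the defective CDF. Cells with
fewer than 10 trials collapse to a single bin carrying only the choice
probability. The original analyses used a Matlab toolbox whose internal
objective is not published; the quantile-multinomial objective is the
standard substitute and is sufficient for the parameter-recovery results
below. Optimization is Nelder–Mead from 10 seeded starts around EZ-style
method-of-moments initial values (first start unperturbed); the best
log-likelihood wins, with ties broken by the smaller parameter-vector
norm. Parameters are transformed to an unconstrained scale
(\(\log a\), \(\mathrm{logit}(z/a)\), \(\log t_0\)) so every Nelder–Mead
iterate is a valid parameter set. Designs declare each parameter
`"shared"` or `"free"` across conditions, and models are compared by
\(\mathrm{BIC} = k \ln n - 2 \log L\).

Recovery, verified in the acceptance suite at 50,000 trials per
condition: drift, threshold and non-decision time return within 5%
relative error and starting points within 10% for the two-coherence
joint fit, the single-condition high-drift fit, and the bias-condition
fit in which only the starting point is free.

```{r recovery}
lo <- ddm_params(v = 0.060, a = 0.151, z = 0.151 / 2, t0 = 0.435)
hi <- ddm_params(v = 0.172, a = 0.151, z = 0.151 / 2, t0 = 0.402)
trials <- ddm_simulate(list(low = lo, high = hi), n = 50000, seed = 1)
design <- fit_design(c("low", "high"), drift = "free", threshold = "shared",
                     start_point = "shared", ndt = "free")
ddm_fit(trials, design, seed = 2)
```

# The three-layer network

The network's equations were not published in the article this analysis
follows (they live in its supplementary material); the module therefore
adopts the standard ingredients the text describes and tunes them until
the published qualitative predictions hold. All units are leaky
firing-rate populations integrated at 1 ms:

- **Accumulation layer**: two leaky competing accumulators,
  \(\dot x_i = S_i - k x_i - w x_j + \text{noise}\), clamped at zero.
  With leak balancing inhibition (\(k = w = 2\)) the difference
  \(x_1 - x_2\) performs a drift-diffusion with drift \(2c\), where the
  stimulus supplies \(1 + c\) to the correct side and \(1 - c\) to the
  other.
- **Threshold layer**: bistable switch units
  \(\tau \dot y = -\lambda y + \alpha\,\sigma(\beta(y - \theta)) + u x + b\)
  with \(\tau = 50\) ms, \(\lambda = \alpha = 1\), \(\beta = 8\),
  \(\theta = 0.7\). This configuration is quiescent below a critical
  input near 0.33, bistable on (0.07, 0.33) (hence hysteresis), and
  saturated above. The bias current \(b\) raises the pre-stimulus
  baseline toward the tipping point without triggering a response.
- **Response layer**: the same switch-unit form with a lower sigmoid
  offset (0.55), so the units are bistable at rest and latch once
  triggered by threshold-unit input (\(u_r = 0.25\)). Feedback inhibition
  proportional to the response units' sigmoidal output reaches the
  threshold and accumulation layers, ramping up in the last tens of
  milliseconds before the overt response (recorded when a response unit
  passes the midpoint of its two rest states, 0.5) and staying on while
  the unit is up; 150 ms after the response the response units are
  switched off for 200 ms, completing the reset.

The simulated LRP is the averaged threshold-layer difference
(correct-side minus other unit), stimulus- or response-locked. Three
qualitative signatures drive all downstream analyses, and the shipped
defaults were tuned against exactly these (the candidate scan is in
`analysis/00_tune_network.R`):

1. raising the drive separates the response-locked waveforms during the
   rise, giving a positive area between the low- and high-drive curves in
   the pre-peak window;
2. the waveform peak moves closer to the response as drive rises
   (stronger input resists the mounting feedback inhibition longer);
3. the baseline-to-peak height falls as the bias current rises (the
   baseline climbs while the peak, set by the response trigger level,
   barely moves).

Because the continuous feedback inhibition is what shapes the peak, the
peak sits tens of milliseconds *before* the overt response, as empirical
LRPs do. A single free gain maps model activation onto microvolts; only
shapes, orderings and latencies are meaningful, never absolute
amplitudes.

`compare_layer_rmsd()` asks which layer better explains an observed
waveform: both layer-average traces are peak-scaled to the waveform's
height, RMSDs are computed over a response-locked window on the grid of
parameter sets whose median simulated RT falls in a plausibility window,
and the threshold layer's winning fraction is reported (ties split 0.5
each). The self-consistency tests check both directions: waveforms
synthesized from the threshold layer yield a fraction above 0.5, and
accumulator-synthesized waveforms below 0.5.

# The LRP pipeline

Operations follow standard ERP practice, with the specific conventions:

- **Filtering**: 4th-order Butterworth applied forward–backward
  (zero-phase). The conventional LRP cutoff is 4 Hz; the quantitative
  round-trip analyses run at 40 Hz because the 4 Hz kernel smears sharp
  waveform landmarks over roughly ±100 ms, and latency conclusions should
  not depend on the smoothing (results are qualitatively identical at
  either cutoff).
- **Artifact screening**: trials are dropped when a 100 ms running
  average of the eye channel exceeds 100 µV (blinks), any EEG channel
  exceeds 70 µV, per-channel variance leaves [0.1, 80] µV² (the bounds
  are interpreted in µV² although they are conventionally quoted in µV),
  or excess kurtosis exceeds 5. Rules are reported in the precedence
  order blink > amplitude > variance-high > variance-low > kurtosis; the
  blink window length is a free choice (100 ms) since no standard value
  exists.
- **LRP**: per-trial C4−C3 for left-hand responses and C3−C4 for
  right-hand ones, correct trials only, re-epoched to stimulus
  (−200…+1500 ms, baseline −200…0 ms) or response (−600…+200 ms,
  baseline −600…−400 ms), then averaged; grand averages are unweighted
  subject means. A `flip` flag orients recordings whose pre-response
  deflection is negative; every measure operates on the oriented
  waveform.
- **Onset (1DF regression)**: grid search over breakpoints; a slope-zero
  segment is fitted before the breakpoint and a straight line after it;
  the total SSE picks the breakpoint (ties to the earliest) and the
  reported onset is where the rise line crosses the baseline level. On an
  exact flat-then-ramp waveform this returns the corner exactly. The rise
  segment is fitted only up to the half-rise point by default: near the
  peak the average flattens as per-trial peak times spread, and including
  that curvature drags the estimate late. The default search window runs
  from the baseline end to the median RT.
- **Peak**: stimulus-locked, the first local maximum before the
  reference RT, height measured from the waveform at onset;
  response-locked, the last local maximum before the response, height
  from the preceding trough. Local maxima must clear a prominence of 20%
  of the in-window range so that residual-noise wiggles on the averaged
  waveform are not mistaken for peaks; plateaus resolve to their earliest
  sample.
- **Area between curves**: trapezoidal integral of (low − high) over the
  stated window (−250…−150 ms response-locked in the coherence analyses,
  −150…−50 ms for preferred/non-preferred), with end points interpolated
  so the integral covers the requested window exactly. Positive area
  means the high-drift curve sits below the low-drift curve during the
  rise.
- **Neural non-decision time**: stimulus-locked onset plus the absolute
  response-locked peak latency, decomposing \(t_0\) into perceptual and
  motor parts.

# The synthetic-data generator

`simulate_behavior()` delegates to the DDM path simulator; in bias mode
the stimulus direction is drawn with the block's probability and the
drift sign follows the stimulus while the starting point stays put.
`simulate_eeg()` embeds a per-trial lateralized template at C3/C4, signed
by response hand: zero until stimulus + \(d_1\), linear rise to its peak
at response − \(d_2\), linear fall back over 300 ms. Noise is
independent white plus 1/f (spectral exponent 1) per channel, plus a
shared 1/f common-mode term that the C3/C4 difference cancels exactly —
so the difference wave sees only the independent components. Injected
artifacts are each sized to trip exactly one screening rule at the
default thresholds.

What the generator does *not* emulate: real scalp topography and volume
conduction, overlapping ERP components, autocorrelated artifact
structure, trial-to-trial template-shape variability, or any systematic
relation between EEG noise and behavior. Passing the round trip therefore
shows that the measurement chain is unbiased under its own generative
assumptions, not that it is robust to everything real EEG does.

Round-trip study conditions (fixed once): 250 Hz sampling, 300 trials,
8 µV lateralization against 4/4/3 µV white/pink/common noise, delays
\(d_1 = 180\) ms and \(d_2 = 100\) ms, 40 Hz pipeline cutoff, 100 seeds.
The 8 µV amplitude sits at the top of the empirically reported LRP range
and gives the averaged waveform the visually clean quality the measures
were designed around (averaged noise ≈ 0.5 µV); at lower amplitudes the
onset estimator's dispersion grows well beyond the ±2-sample target long
before its median moves. Medians over seeds recover onset, peak latency
and neural \(t_0\) within two samples (8 ms).

# Cross-subject statistics

`robust_regression()` wraps iteratively reweighted least squares with
Tukey bisquare weights (tuning constant 4.685 — the estimator family was
not named in the original analysis, so the standard choice is used); on
exact-line data it returns the OLS solution, and p-values use a
t-reference with \(n - 2\) degrees of freedom. The within-subject
peak-height/starting-point relation is tested by per-subject OLS slopes
against zero (`within_subject_slope_test()`), which is the package's
reading of a repeated-measures analysis with a continuous within factor.
`paired_area_test()` computes per-subject areas between two curves and
tests them against zero, with degenerate zero-variance inputs reported as
\(t = \pm\infty\) with a flag rather than an error.

# Problem sizes and numerical choices

The acceptance-scale analyses use 50,000 trials per condition for the
recovery fits (about a minute each), 20,000-trial Monte-Carlo checks of
the closed forms (Table-set parameters plus five random valid sets),
250-trial network ensembles per drive/bias level, and 100 seeds for the
EEG round trip. Unit tests run the same checks at smaller sizes. Other
fixed choices: series truncation \(10^{-10}\); CDF tail truncation
\(10^{-12}\); optimizer relative tolerance \(10^{-9}\) with at most 3000
iterations; bin-probability floor \(10^{-12}\); sample/ms conversions
round half away from zero.

# Known limitations

- The network module is a qualitative instrument: its parameter values
  are a tuned exemplar, not estimates, and nothing maps activations to
  microvolts beyond one gain.
- The fit engine implements the pure DDM only; across-trial variability
  in drift, starting point or \(t_0\) is out of scope, so data generated
  with such variability will be misfit.
- With near-ceiling accuracy (as in the high-drift single-condition set)
  the minority-choice cell is empty and threshold/starting point are
  weakly identified; drift and \(t_0\) remain well recovered, and only
  those are asserted.
- The 1DF onset estimator is biased toward early onsets at low SNR (the
  earliest above-baseline fluctuation wins); the round-trip conditions
  keep SNR high enough that the median bias stays within two samples.
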