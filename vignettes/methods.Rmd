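---
title: "Inferring latent drift-diffusion parameters from swim events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring latent drift-diffusion parameters from swim events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ddmfit` infers the latent parameters of a bounded Ornstein-Uhlenbeck
decision process from event-based behavioral data, the motivating case being
swim bouts of larval zebrafish following random-dot motion. A decision
variable $x_t$ integrates stimulus evidence,

$$dx_t = \left(\mu f(I_t) - \lambda x_t\right)dt + \sigma\, dW_t,
\qquad f(I) = \sqrt{I},$$

between absorbing bounds at $\pm B$. A bound hit is a decision event —
`correct` at $+B$ (motion-following), `incorrect` at $-B$ — after which the
state is partially reset to $r\,\mathrm{sign}(x)B$ and frozen for a delay
$\delta$. The five free parameters and their units:

| parameter | meaning | units | default search range |
|---|---|---|---|
| $\sigma$ | diffusion (integration noise) | $B\,s^{-1/2}$ | $[0.05, 3]$ |
| $\mu$ | drift gain on $f(I)$ | $B\,s^{-1}$ | $[0, 8]$ |
| $\lambda$ | leak ($<0$: self-reinforcing) | $s^{-1}$ | $[-8, 8]$ |
| $r$ | post-decision reset fraction | — | $[0, 1]$ |
| $\delta$ | post-decision freeze | s | $[0, 1]$ |

The bound is redundant — scaling $B$, $\sigma$, $\mu$ together leaves the
event statistics unchanged (the package tests this directly) — so $B = 1$
always, and it is not fitted. The input exponent is fixed at $0.5$: left
free it is not reliably identifiable and destabilizes repeated fits.

The simulator integrates with explicit forward Euler at `dt = 0.01` s; no
accuracy gain was found below that and instabilities appear near 0.1 s.
Bound hits are detected at step ends without within-step interpolation, so
the timing error is below one `dt`. The stochastic increment is
$\sigma\sqrt{dt}\,\mathcal N(0,1)$: with standard-deviation (rather than
variance) scaling by the step, event statistics are comparable across `dt`,
which is the stated purpose of the scaling. The delay is implemented as
$\lceil\delta/dt\rceil$ frozen steps beginning the step after the event;
events are points in time, so the inter-event clock runs through the delay.
Each coherence level forms one continuous session: the state starts at
$x_0 = 0$ and is *not* reset at trial boundaries within a session,
preserving persistent-state effects across the rest phases (where $I = 0$
but the process keeps evolving; rest-phase events are recorded and excluded
from fitting). A guard aborts with a diagnostic if $|x| > 10B$, which only
pathological leak values can reach between events.

## Histograms and the loss

Events are summarised as labeled inter-swim-interval (ISI) histograms per
(coherence, label) pair: stimulus-phase events at least 2 s after stimulus
onset (steady state, skipping onset adaptation), intervals in $[0, 2)$ s,
bins of 0.05 s (five simulation steps, for robust binning of simulated
events). Counts are divided by the total analysed stimulation time.

Two height conventions are supported via `height_convention`. The default,
`"per_bin"`, divides counts by time only, so a height is "events per second
falling in this bin" and the histogram area $A = \sum_\tau h(\tau)$ is the
labeled event rate in events/s. The alternative `"density"` additionally
divides by the bin width. The package defaults to `per_bin` because the
model-acceptability thresholds below ($A \ge 0.005c$, $A(1) > 0.01$,
$h \le 0.15$) are mutually consistent with the observed regime of roughly
one swim per second only in those units: under the density reading the
$h \le 0.15$ cap would restrict total event rates to about $0.3$/s,
contradicting the regime the criteria are meant to admit. The conventions
differ only by the constant $1/\Delta\tau$, so switching rescales the loss
but not any argmin.

Distances between histogram sets use a height-weighted Kullback-Leibler
divergence,

$$D^*_{KL}(P_0, P_1, P_2) = \sum_n P_0(n)\,P_1(n)\ln\frac{P_1(n)}{P_2(n)},$$

with $P_0$ the target histogram as bin weight, so errors at tall peak bins
dominate errors in flat tails. Because the divergence is asymmetric, both
orientations $d_0 = D^*(P_t, P_t, P_m)$ and $d_1 = D^*(P_t, P_m, P_t)$ are
computed and the larger taken; the total loss averages over the eight
(coherence, label) pairs. Zero denominators are clamped at
$\varepsilon = 10^{-6}\max(1, \max P_1)$ and $0\cdot\ln(\cdot) := 0$, which
preserves exact zero at equality and bounds single-bin contributions; pairs
empty on both sides contribute zero. The unweighted $D_{KL}$ is available
via `metric = "dkl"` for comparison.

## Model library

`build_library()` rejection-samples parameter sets uniformly over the
search space and keeps those whose simulated histograms (continuous
segments, 900 s per coherence by default — the per-coherence data volume of
a standard session) satisfy seven acceptability inequalities: minimum
correct activity scaling with coherence ($A_c(c) \ge 0.005c$), minimum
incorrect activity scaling against it ($A_i(c) \ge 0.005(1-c)$), activity
at full coherence ($A_c(1) > 0.01$ or $A_i(1) > 0.01$), a growth-and-
dominance clause in either orientation ($A_c(1) > 1.33 A_c(0)$ and
$A_c(1) > 3.33 A_i(1)$, or the mirrored incorrect-dominant version), and
per-bin height caps $h \le 0.15$ for both labels (no unnaturally regular
event trains). The default search ranges (table above) admit event rates of
roughly 0.1–3 events/s without saturating $r$ or $\delta$; with them the
rejection sampler accepts on the order of 10% of draws. Every stored model
records its simulation seed, so reference histograms are exactly
reproducible.

## Fitting

`fit_ddm()` minimizes the loss by Bayesian optimization. Parameters are
scaled to the unit cube; a Gaussian-process surrogate with a Matern 5/2
covariance is fitted to the observed *log*-losses (the loss spans orders of
magnitude near its noise floor, and the log transform keeps the bottom of
the basin resolved by a stationary kernel). GP hyperparameters
(lengthscale, noise variance) maximize the marginal likelihood over a small
grid, re-selected every `refit_every = 10` iterations. After `n_init`
uniform random evaluations, each iteration scores a candidate set (400
uniform points plus local Gaussian perturbations of the incumbent at three
scales) under three acquisition functions — lower confidence bound
($\kappa = 1.96$), expected improvement and probability of improvement
($\xi = 0.01$) — and picks among their proposals probabilistically with
softmax-weighted hedge gains, updated by the surrogate mean at each
strategy's proposal. These acquisition settings are recorded in every
`fit_result`.

Each function call simulates the candidate for `trials_per_eval`
repetitions per coherence under the evaluation protocol and compares
histograms. The evaluation protocol defaults to the protocol the *target*
was built under: evaluating under a different session structure than the
target's generating process introduces a small systematic histogram
mismatch that biases the optimum. The loss is stochastic; the simulation
seed of call $j$ is a fixed function of the master seed and $j$ (common
random numbers across proposals at the same index), which reduces surrogate
noise without biasing the argmin, and makes entire fits reproducible
bit-for-bit. The reference scale is 1,500 calls with 100 random
initializations and 2,000 trials per evaluation; the `"desk"` preset (300
calls, 50 initializations, 300 trials) is the reduced configuration used
throughout the package's own validation suite.

Recovery quality is measured by the normalized error
$e(j) = |p(j) - p_{target}| / |m_{max} - m_{min}|$ per parameter (and
$d(j)$, the same functional against the final estimate, when the truth is
unknown). Two caveats the validation makes visible: the loss surface has a
genuine ridge along which leak, diffusion and drift partially compensate,
so single low-rate models can fit wrong parameter combinations about as
well as the truth at desk scale; and at small `trials_per_eval` the
model-side histogram sampling noise adds a loss penalty that differs
between candidate models, slightly favoring high-event-rate candidates.
Both shrink with evaluation effort. Measured across a 10-model library at
desk scale, the median normalized errors for diffusion, drift and delay sit
below 0.10, 0.10 and 0.06 of their range widths, while leak and reset land
near 0.15-0.18 — the parameters the ridge leaves least constrained; for the
affected models the expected loss at the fitted parameters is at or below
the expected loss at the truth, so the residual error reflects the
information in the data at these evaluation budgets, not the search.

## Validation experiments

* **Sensitivity.** For each library model, a reference simulation is
  compared against simulations with one parameter perturbed by a signed
  fraction of its search-range width (grid $\pm5, \pm10, \pm25, \pm50\%$ —
  chosen so the two reported significance onsets are grid points).
  The baseline is the loss between two independent simulations of the
  unperturbed model — the only comparator that is null by construction.
  Each signed level is compared against the baseline with a two-sided
  Mann-Whitney U test at $\alpha = 0.05$ (`stats::wilcox.test`);
  perturbations leaving the search space are skipped, not imputed. The
  significance onset of a parameter is the smallest grid magnitude carrying
  a significant level (`sensitivity_onsets(rule = "any")`); a stricter
  convention requiring both signs to reject is available (`rule = "all"`).
  Onsets near the grid's resolution are seed-sensitive: the reset factor's
  $\pm10\%$ p-values straddle $\alpha$ across library realizations, so its
  reported onset can alternate between neighboring grid magnitudes, while
  the diffusion onset is stable.
* **Duration sweep.** Targets are generated at several total dataset
  durations, fitted, and the per-parameter errors compared against
  non-optimized uniform random draws (whose expected normalized error is
  $1/3$) with a one-sided Mann-Whitney U test per duration.
* **Histogram-noise robustness.** `add_histogram_noise()` perturbs each bin
  with i.i.d. $\mathcal N(0, \sigma^2)$ noise; negative heights are clipped
  to zero (heights are rates) and the clipped fraction reported.
* **Statistics.** The bootstrap median test pools both groups, resamples
  at the original sizes 10,000 times, and reports the fraction of resampled
  absolute median differences reaching the observed one (so identical
  groups give exactly $p = 1$); the median CI is the 5th–95th percentile
  interval of bootstrapped medians. The CV uses the sample (n−1) standard
  deviation — group sizes are small. Trend tests across ordered groups are
  plain OLS with the slope t-test.

## Synthetic data

Two generators make every validation experiment self-contained.
`gen_target_dataset()` wraps simulation plus histogramming for
model-generated targets; its defaults (four coherence levels 0/0.25/0.5/1,
900 s per coherence, `dt = 0.01`) are the conditions of the standard
session design (trials of 10 s rest / 30 s stimulus / 10 s rest, 30 trials
per coherence, with the first 2 s after onset excluded as adaptation).
`gen_orientation_trace()` builds heading-orientation traces at 90 Hz with
raised-cosine turn bouts plus Gaussian per-frame jitter (default 0.1°,
well below the detection threshold). It emulates discrete reorientation
events on a quiet baseline; it does not emulate slow drift, tracking
dropouts, head-tail swaps or wall interactions, so passing round-trip tests
demonstrate correctness of the detector logic, not robustness to every
tracking artifact of real video — that is what the QC layer is for.

Swim extraction mirrors the tracking pipeline: centered rolling variance of
orientation in a 50 ms window (population estimator — the thresholds are
empirical, and the choice only rescales them slightly; documented so they
can be recalibrated), hysteresis detection (start above 1 deg² sustained
20 ms, end below 0.5 deg² sustained 50 ms), turns within ±3° excluded as
forward swims, labels assigned by turn direction against the stimulus
(0%-coherence trials use the trial's nominal counterbalanced direction).
QC applies the six tracking filters (ISI < 30 s, speed < 6 cm/s, area
< 2000 px, |turn| ≤ 150°, >5% flagged swims drops the trial, mean rate
< 0.375 swims/s drops the animal); criteria whose inputs are absent are
skipped and noted in the report. QC runs before the forward-swim band is
applied to percentages; the first event of a segment has no ISI and never
enters histograms.

## Problem sizes in the test suite

The package's automated checks run reduced problem sizes chosen as a
deliberate design point: recovery uses 10 library models at the desk
preset; the sensitivity suite uses 20 models at 900 s per coherence (the
size at which the onset grid is informative); the duration sweep uses 3
models at budget 60; bootstrap calibration uses 500 null pairs of n = 20.
The reference-scale experiments (1,500 calls × 2,000 trials, 100-model
libraries, full duration grids) use identical code paths — only the size
arguments differ.

## Known limitations

* Time-varying $\sigma(t), \mu(t), \lambda(t)$ are not supported; the
  model treats them as constants.
* The fitted exponent of $f(I)$ is fixed at 0.5 by design (see above).
* Parameter identifiability is uneven: diffusion is the most sensitive
  parameter, the reset factor the least; near-flat loss regions around the
  optimum leave residual run-to-run variation that `repeat_fit()`
  quantifies.
* Whether the original tracking used sample or population variance, and
  whether integrator state persists across trials, are not stated in the
  source experiments; the package's choices (population variance,
  persistent state within a session) are documented and configurable where
  they matter.
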