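# ddmfit

Simulation-based inference of latent drift-diffusion parameters from
event-based decision data.

## The problem

Larval zebrafish (and many other animals) respond to whole-field visual
motion with discrete decision events — swim bouts that either follow the
motion direction ("correct") or go against it ("incorrect"). The timing and
labeling of these events across task difficulties carry information about
the hidden evidence-accumulation process, but the process itself is not
observable. `ddmfit` is for experimentalists and modellers who want to turn
tables of decision events (or raw heading-orientation traces) into
interpretable, per-individual estimates of the latent parameters of a
drift-diffusion model.

The model is a bounded Ornstein-Uhlenbeck process for the decision variable
$x_t$,

$$dx_t = (\mu f(I_t) - \lambda x_t)\,dt + \sigma\,dW_t, \qquad f(I)=\sqrt I,$$

with absorbing bounds at $\pm B$ ($B = 1$; it is redundant with $\sigma$ and
$\mu$). A bound hit emits a decision event (sign = label), partially resets
the state to $r\,\mathrm{sign}(x)B$, and freezes it for a delay $\delta$.
The five free parameters are the diffusion $\sigma$, drift $\mu$, leak
$\lambda$ (negative = self-reinforcing), reset fraction $r$, and delay
$\delta$.

Fitting minimizes a height-weighted Kullback-Leibler divergence
$D^*_{KL}(P_0,P_1,P_2) = \sum_n P_0(n) P_1(n) \ln(P_1(n)/P_2(n))$ between
time-normalized inter-swim-interval histograms (4 coherence levels x
correct/incorrect; evaluated in both orientations, larger value taken,
averaged over the 8 pairs) by Bayesian optimization with a Gaussian-process
surrogate. The package also implements the surrounding validation suite:
acceptability-filtered random model libraries, parameter-recovery error
$e(j) = |p(j)-p_{target}|/|m_{max}-m_{min}|$, perturbation sensitivity with
Mann-Whitney tests, dataset-duration sweeps, histogram-noise robustness,
and bootstrap median tests/intervals — plus the front-end that extracts and
quality-controls swim events from 90 Hz orientation traces.

## Worked example

Sample a biologically plausible model, simulate a session-sized dataset from
it, and recover its parameters:

```r
library(ddmfit)

sp <- search_space()   # sigma [0.05,3], mu [0,8], lam [-8,8], r [0,1], delta [0,1]
lib <- build_library(sp, n_models = 2, duration_per_coherence = 900, seed = 101)
truth <- lib$models[[2]]$params
tgt <- gen_target_dataset(truth, duration_per_coherence = 900, seed = 1002)
print(tgt$hists)
#> Labeled ISI histograms: 40 bins of 0.05 s, 4 coherences x 2 labels ( per_bin )
#>   event rates (events/s):
#>                0   0.25    0.5      1
#> correct   0.2650 0.6225 0.7149 0.8508
#> incorrect 0.2673 0.0590 0.0267 0.0122
#>   intervals outside range: 188
```

The printed matrix is the labeled event rate (events per second of analysed
stimulation) per coherence level: correct swims rise from 0.27/s at 0%
coherence to 0.85/s at full coherence while incorrect swims vanish — the
psychometric signature of a drifting integrator.

```r
fit <- fit_ddm(tgt$hists, sp, preset = "desk", seed = 202)  # 300 calls, ~1 min
print(fit$best_params)
#> Drift-diffusion parameters (bound B = 1 )
#>   sigma (diffusion)   1.1915  1/sqrt(s)
#>   mu    (drift)       2.6922  1/s
#>   lam   (leak)       -0.4731  1/s
#>   r     (reset)       0.0935
#>   delta (delay)       0.8152  s
round(estimation_error(fit$best_params, truth, sp), 3)
#> sigma    mu   lam     r delta
#> 0.018 0.046 0.034 0.092 0.005
```

Recovery errors are reported as fractions of each parameter's search-range
width; here every latent parameter is retrieved within 2-9% of its range at
desk scale (the reference configuration is `budget = 1500,
trials_per_eval = 2000`). Identifiability is not uniform across the space:
the loss surface has a ridge along which diffusion, drift and leak partly
compensate, so some parameter sets recover less sharply — the methods
vignette quantifies this.

Swim-event extraction from an orientation trace works the same way end to
end:

```r
tr <- gen_orientation_trace(10, bout_times = c(2, 4, 6),
                            bout_angles = c(20, -15, 25), seed = 2)
sw <- label_swims(detect_swims(tr))
qc <- qc_filter(sw, total_time_s = 10)
```

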