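# dnfip — dynamic neural fields with intrinsically plastic gain and bias

Dynamic neural fields (DNFs) model the activation `u(x, t)` of a
homogeneous recurrent neural population over a continuous feature
dimension `x` (here: contact orientation, periodic over 0–360°):

    tau * du(x,t)/dt = -u(x,t) + S(x,t) + ∫ w(|x - x'|) g(u(x', t)) dx'

with a Mexican-hat interaction kernel
`w(d) = c_exc exp(-d²/2σ_exc²) - c_inh exp(-d²/2σ_inh²)` (short-range
excitation, long-range inhibition) and a logistic output
`g(u) = 1 / (1 + exp(-(a u + b)))`. The gain `a` and bias `b`
(equivalently, the resting level `h = b/a`) decide where the field's
detection instability sits — and the right values depend on the input
distribution, which in sensor-driven applications is unknown and drifts.

This package implements online **intrinsic plasticity (IP)** for the
whole field: a homeostatic rule that adapts the *global* `(a, b)` so the
distribution of the scalar output measure `y(t) = max_x g(u(x, t))`
matches an exponential target with mean `mu` (sparse, mostly-silent
output with occasional detections). With the input measure
`z(t) = u(argmax_x g(u), t)`, the rules descend the Kullback–Leibler
divergence to the target:

    db/dt = eta * (1 - (2 + 1/mu) y + y²/mu)
    da/dt = eta / a + z * db/dt

optionally corrected by the **natural gradient**: the Euclidean gradient
is premultiplied by `(F + eps I)^-1`, where `F` is an online
(exponentially smoothed) Fisher-information estimate from per-sample
gradient outer products — markedly faster and free of the plain
gradient's transient gain collapse when the input mean shifts.

The package also provides a population-coded synthetic tactile input
generator (0–2 contacts per frame at opposing orientations, circularity
in (0, 1) setting amplitude, Gaussian orientation blur, ~3.33 fps,
optional looping and scale/offset manipulations), sliding-window
evaluation statistics (output histograms, input–output correlation,
convergence monitoring), and reproducible experiment runners.

## Worked example

Thirty simulated minutes of stationary synthetic input (amplitudes in
[0, 6]) through the standard preset (100 sites, kernel 14/2/7/6,
`tau` 0.1 s, Euler step 10 ms, initial `a = 1`, `b = -5`,
natural-gradient IP with `eta = 0.001`, `mu = 0.2`):

```r
library(dnfip)
run <- run_experiment(experiment_config("mean_sweep", mu = 0.2, seed = 1))
print(run)
#> dnf_run [mean_sweep, mu = 0.2, seed = 1]
#>   final gain 0.5284, bias -3.088
#>   mean y: 0.2107 (pre-switch) -> 0.2107 (final window)
#>   final-window KLD vs exp(mu): 0.415 nats
```

The gain/bias converge (here to 0.53 / −3.09), and the 5-minute sliding
mean of the output measure settles at 0.21 — the configured target mean.
Comparing natural-gradient and plain-gradient adaptation on the
offset scenario (input shifted from [0, 6] to [−12, −6] at minute 20):

```r
cmp <- compare_gradients(experiment_config("offset_ng", mu = 0.2, seed = 1))
print(cmp)
#> gradient comparison on the offset scenario
#>   recovery: NG 2.06 min vs plain 66.96 min
#>   post-switch gain minimum: NG 0.1516 vs plain 0.09421
#>   final gain: NG 0.4878 vs plain 0.445
```

The natural gradient restores the output statistics in ~2 simulated
minutes; the plain gradient first collapses the gain (the
input-variance-overestimation transient) and needs over an hour.
`plot_run(run)` draws the histogram-over-time panels;
`inst/scripts/dnfip-cli` exposes `generate-input`, `run`,
`compare-gradients` and `plot` from the shell.

## Layout

- `R/` — grid/kernel construction, field dynamics, IP learning rules
  (plain and natural gradient), synthetic input generator, sliding
  statistics, experiment runners, base-graphics plots.
- `vignettes/dnf-intrinsic-plasticity.Rmd` — the model, its parameters
  and the numerical and design choices, with known limitations.
- `tests/testthat/` — unit and property tests (brute-force convolution
  oracles, closed-form relaxation, quadratic-root and finite-difference
  learning-rule oracles, hysteresis, destabilization, determinism).
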