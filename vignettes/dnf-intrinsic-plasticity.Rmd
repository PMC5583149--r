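---
title: "Self-adapting dynamic neural fields: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-adapting dynamic neural fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dnfip)
```

## The model

A one-dimensional dynamic neural field (DNF) describes the activation
`u(x, t)` of a homogeneous recurrent population over a feature dimension
`x` — here the orientation of a tactile contact, periodic on 0–360° and
sampled at `n_sites` points:

    tau du/dt = -u + S(x, t) + sum_j w(d(x, x_j)) g(u(x_j, t))

The `-u` term makes the dynamics relaxational; `S` is the external
input; the interaction kernel `w` is a difference of Gaussians
(short-range excitation `c_exc, sigma_exc`, long-range inhibition
`c_inh, sigma_inh > sigma_exc`) producing winner-take-all competition;
and the output nonlinearity is a logistic with global gain and bias,
`g(u) = plogis(a u + b)`. There is no separate additive resting level:
the bias encodes it as `h = b / a`, so `-b / a` is the detection
threshold in activation units. Integration is explicit Euler with step
`dt <= tau`.

Depending on where `S + recurrence` sits relative to the threshold, the
field is in one of three regimes: low-stable (silent), bistable
(silent and peaked states coexist — the source of detection hysteresis),
and high-stable (peak). The transitions are the detection and reverse
detection instabilities; the test suite asserts the hysteresis between
them by ramping a localized input up and down.

Two scalar measures summarize the field for learning: the output
measure `y(t) = max_x g(u(x, t))` (the field's confidence in its current
detection, in (0, 1)) and the input measure `z(t) = u(argmax g, t)`,
the activation behind that output — deliberately *including* recurrent
contributions. Ties in the argmax are broken toward the lowest site
index; since the logistic is strictly increasing, `z = max(u)`.

## Intrinsic plasticity

Intrinsic plasticity (IP) adapts `(a, b)` online so that the
distribution of `y` over time approaches an exponential with mean `mu`
— a sparseness constraint: mostly silent, occasionally detecting.
Gradient descent on the Kullback–Leibler divergence between the output
distribution and that target yields

    db/dt = eta (1 - (2 + 1/mu) y + y^2 / mu)
    da/dt = eta / a + z db/dt

The bias rule is a downward-opening quadratic in `y`: positive below its
smaller root (raise the resting level when the field is silent),
negative above it (lower it when active). The gain rule couples the
input strength into the same direction and adds an unconditional upward
drift `eta / a`. Jointly they park the field at the edge of the
detection instability, which is what keeps it sensitive to its input.

With the natural gradient, the per-sample Euclidean gradient
`grad = (-da-rate, -db-rate)` (learning rate factored out) first updates
a 2×2 Fisher-information estimate by exponential smoothing,
`F <- (1 - lambda) F + lambda grad gradᵀ`, and the parameter step is
`-eta (F + eps I)^{-1} grad` with an exact, Tikhonov-regularized 2×2
inversion. The metric equalizes the very different sensitivities of `a`
and `b` (the gain gradient scales with `z`), which is what prevents the
plain gradient's transient gain collapse when the input mean shifts.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `n_sites` | 100 | — | grid resolution over 360° |
| `tau` | 0.1 | s | field time constant |
| `dt` | 0.01 | s | Euler step |
| `c_exc`, `sigma_exc` | 14, 2 | weight, sites | local excitation |
| `c_inh`, `sigma_inh` | 7, 6 | weight, sites | surround inhibition (stored positive, always subtracted) |
| `a`, `b` (initial) | 1, −5 | —, activation | gain and bias; threshold starts at 5 |
| `eta` | 0.001 | per update | learning rate |
| `mu` | 0.2 | — | target output mean (0.1 also studied) |
| `lambda` | 1e-4 | — | Fisher smoothing (`tau`/1000; 0.01 circulates as an alternative) |
| `eps` | 1e-4 | — | Tikhonov regularization |

## Numerical and design choices

**Sign of the transfer.** The printed form of the parametric logistic,
`(1 + exp(-a x + b))^{-1}`, is inconsistent with the reported negative
biases: at `u = 0` it would saturate the output, while the model
requires silence without input. We use `plogis(a u + b)`, under which
`b = a h` with negative `h` acts as a detection threshold at
`u = -b / a`, consistent with every reported parameter value and with
the adaptation directions of the learning rules.

**Kernel discretization.** The convolution is a plain discrete sum over
sites — no site-spacing weight. The kernel strengths in the standard
preset, however, are read as *integrated* lateral weight (each Gaussian
divided by its own `sqrt(2*pi)*sigma`; `make_kernel(..., normalized =
TRUE)`), the convention of common neural-field software. The peak-value
reading of 14/2/7/6 puts the field deep in the self-sustaining memory
regime — a bare peak of `u ≈ 21` persists with no input at the reported
converged `(a, b)` — where the output decouples from the input, no
input–output correlation is possible, and the adaptation cannot
converge. Under the integrated-weight reading the same numbers place
the field exactly in the input-driven detection regime: peaks form
under strong contacts and die when the contact leaves. `make_kernel`
defaults to the plain peak-value form for generality; every preset and
experiment uses the normalized convention.

**Update cadence.** The learning rules are difference rules. Read as
continuous-time rates integrated per Euler step (`cadence = "step"`),
the maximum bias drift is `eta` per second, which is a factor ~3 too
slow to reproduce the reference adaptation time courses (initial
convergence within 20 simulated minutes; the plain-gradient bias
climbing ~+7 within its 80 post-switch minutes). Read as per-update
increments applied once per input frame — a realtime processing loop at
3.33 fps — they reproduce those timescales. The frame cadence is the
default; both are available.

**Frame rate.** The generator defaults to 10/3 fps so that one frame
(0.3 s) is exactly 30 Euler steps; the zero-order hold presents each
frame for `floor(frame_dt / dt)` steps.

**Degenerate inputs and safety.** The logistic is computed via
`plogis`, stable in both tails. The gain is clamped below at 1e-6 after
every update, keeping the transfer orientation-preserving and the
`eta / a` term finite. Non-finite activations abort with the offending
step index. With zero blur the input bump degenerates to its nearest
grid site. Sliding windows are trailing and half-open, `(t - w, t]`;
a window with zero variance in either series yields a missing
correlation value, never a silent zero.

## The synthetic input generator

The generator emulates a two-fingered tactile exploration stream: per
frame 0, 1 or 2 simultaneous contacts (probabilities 0.3/0.4/0.3; two
contacts sit at opposing orientations 180° apart), each with a
circularity in (0, 1) drawn from Beta(2, 5) — right-skewed, so highly
circular contacts are a minority — scaled by 6 activation units and
blurred with a circular Gaussian of 10.8° (3 sites). Contact
configurations persist for a geometric number of frames (mean 2),
giving the slowly varying stripes of a real exploration. A 315 s block
is generated and looped for the experiment runs, emulating a repeated
recording period. Manipulations (scale by 1/6 or 6, offset −12) apply
to all frames from the switch time on.

What it does not emulate: tactile-sensor physics, the true circularity
distribution and temporal statistics of recorded manipulation data, and
correlations between orientation and circularity. Passing tests
therefore show that the adaptation works as specified on a plausible
population-coded stream, not that it reproduces any particular
recording.

## Experiment protocol and problem sizes

Experiments run the 100-site preset at `dt` = 10 ms. The stationary
runs last 30 simulated minutes (180,000 Euler steps); manipulation runs
20 minutes before the switch and 30 after (300,000 steps); the
plain-gradient offset run extends to 100 minutes because its recovery
is an order of magnitude slower. Summary statistics use 5-minute
trailing windows (one full input loop). Recovery time is defined on the
sliding output mean: the first post-switch time at which it re-enters a
±25% band around its pre-switch value after having left it — a band on
the windowed mean, since the instantaneous output is bimodal by design.
Convergence of `(a, b)` is declared when both stay within 2% of their
trailing 5-minute means for a full further window.

## Known limitations

- Compensating a variance change with the gain shifts the balance
  between input and recurrence: after ÷6 down-scaling the output
  statistics recover, but the output mean can be restored with few true
  detection peaks, and after ×6 up-scaling the output is more strongly
  input-driven. This is a property of the method, visible in the final
  empirical divergence, not a numerical artifact.
- Near-zero input destabilizes the adaptation by design: the gain grows
  until recurrence alone sustains output, which the rules then tear
  down — a perpetual on–off oscillation, asserted as a property test.
- The target mean is matched in distribution over a window, not
  tracked instantaneously; `mu` outside roughly (0.05, 0.5) pushes the
  bias-rule roots into regions where matching degrades.
- Only one-dimensional periodic (or zero-padded) fields are supported.
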