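---
title: "A two-timescale double-well model of perspective-taking decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-timescale double-well model of perspective-taking decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perspectr)
```

## The model

`perspectr` treats a perspective-taking decision as competition between two
continuously evolving coordinates, each living on the tilted quartic
potential

$$V(x) = kx - \tfrac{x^2}{2} + \tfrac{x^4}{4},$$

whose two local minima stand for the two perspectives a responder can
settle into: the negative well is egocentric, the positive well
other-centric. The tilt $k$ is the control parameter that biases the
landscape; with our sign convention a *positive* $k$ deepens the
*egocentric* well (the drift at the saddle is $-k$). For
$|k| < 2/(3\sqrt3) \approx 0.385$ both wells exist, separated by a saddle;
beyond that fold only one well survives.

Two processes share this landscape but differ in timescale:

* a **fast, shallow "potentiation" process** $x_P$ — rapid, associative,
  low-level; and
* a **slow "simulation" process** $x_S$ — deliberative, strategic.

They update synchronously, in discrete time, as noisy gradient descent plus
mutual pull:

$$x_{P,t+1} = x_{P,t} - u_P\,(k_P - x_{P,t} + x_{P,t}^3)
  + \alpha\,(x_{S,t} - x_{P,t}) + \mathcal N(0,\sigma)$$
$$x_{S,t+1} = x_{S,t} - u_S\,(k_S - x_{S,t} + x_{S,t}^3)
  + \beta\,(x_{P,t} - x_{S,t}) + \mathcal N(0,\sigma)$$

The single-process map (`step_1d()`) is the same update with unit rate:
$x_{t+1} = x_t + (-k + x_t - x_t^3) + \mathcal N(0, \sigma)$. The rates
$u_P, u_S$ only enter the two-process map; coupling terms are added outside
the $u$-scaled gradient. Each process receives its own independent
standard-normal draw, both scaled by the shared $\sigma$ — independence is
what makes the decoupled system ($\alpha = \beta = 0$) separate exactly
into two one-dimensional processes, a property the test suite exercises.

A **trial** starts at the saddle and maintains signed running sums
$\sum x_P$ and $\sum x_S$ (one addend per step; the initial state is not
summed). The first sum to reach the threshold in absolute value ends the
trial: that process is the *winner*, and the sign of its sum names the
*outcome* (negative = egocentric). This is an accumulator-to-bound decision
rule in the drift-diffusion tradition, with the state variable itself — not
a separate evidence variable — being integrated.

## Parameters

All parameters are dimensionless; time is in map steps.

| parameter | meaning | default | why |
|---|---|---|---|
| $k_P, k_S$ | landscape tilt per process | 0 | unbiased landscape; regimes use $|k| \le 0.2$ |
| $u_P, u_S$ | descent rate per step, $0 < u \le 1$ | 0.2 | canonical fast rate; the slow process uses 0.1 (half) |
| $\alpha$ | pull of fast toward slow (top-down) | 0 | coupling off unless a regime turns it on |
| $\beta$ | pull of slow toward fast (bottom-up) | 0 | idem |
| $\sigma$ | per-step Gaussian noise s.d. | 0.01 | the systematic parameter record for all four regimes |
| threshold | accumulator bound | 30 | the canonical bound used by all regimes |
| max_steps | per-trial step cap | 50000 | guarantees termination; the exact saddle with $\sigma = 0$ never moves |
| init | start state | (0, 0) | "near the saddle" implemented as exactly the saddle; the first noisy step supplies the perturbation, avoiding an undocumented jitter parameter |

The equal-process regime is quoted at two noise levels, $\sigma = 0.01$
and $\sigma = 0.1$. The presets use $\sigma = 0.01$, the value shared by
all four regimes; the other value can always be requested (`sigma` override
in configs, flags, or `perspective_model()`), and the acceptance suite
checks the equibias property under both — the regime is symmetric, so both
pass.

## The four canonical regimes

`preset()` returns the four demonstration configurations; `simulate()` (or
`run_batch()`) runs them and `replicate_figure()` attaches each regime's
qualitative verdict:

* **fig2 — equibias.** Identical untilted processes, no coupling. Decided
  trials split evenly between the poles; at $n = 2000$ the other-centric
  proportion stays within three binomial standard errors of 0.5.
* **fig3 — fast egocentric dominance.** $k_P = 0.2$, $u_S = u_P/2$. The
  fast process races to its (egocentrically tilted) well and crosses the
  bound first in essentially every trial; unanimity of 50-trial batches
  holds in ≥ 99 of 100 seeds.
* **fig4 — slow-strategy dominance.** The slow process carries an
  other-centric tilt ($k_S = -0.2$) and pulls the fast process
  ($\alpha = 0.2$): other-centric outcomes dominate (≥ 95%) despite half
  the rate and an opposing fast tilt.
* **fig5 — coherence.** Mutual coupling ($\alpha = 0.2$, $\beta = 0.01$)
  with a slight other-centric slow tilt ($k_S = -0.025$): mixed responding,
  each decision jointly reinforced by both processes.

### What "coherence speeds decisions" does and does not mean here

With mutual coupling the two processes drag each other into the same well,
and decisions are faster than under *one-way* coupling: at the fig5 tilts,
turning $\beta$ from 0 to 0.01 lowers mean steps-to-decision (about 58 vs
61 at $n = 1000$; the unit suite asserts the direction, not the values).
That is the controlled contrast for "processes pulling each other".
Removing *both* couplings instead removes the only brake on the tilted fast
process, which then races to the bound unopposed in ~35 steps — so the
fully uncoupled variant is *faster* than the coherent one. A speed
comparison against $\alpha = \beta = 0$ therefore fails by construction in
this model, and the acceptance suite documents that comparison as a known
failing check rather than weakening it.

## Landscape analysis

The vector field drawn by `plot()` is the one-step displacement of the
noise-free map, $\mathrm{step}(x) - x$, sampled on a grid
(`vector_field()`); the
model is only ever defined as a discrete-time map, so no continuous-time
flow is constructed. Default grid: $[-1.5, 1.5]^2$ at 21 points per axis,
covering every attractor for $|k| \le 0.3$.

Fixed points (`fixed_points()`) are found by damped Newton iteration on the
displacement from every grid node, using the analytic Jacobian

$$J = \begin{pmatrix} 1 - u_P(3x_P^2 - 1) - \alpha & \alpha \\
\beta & 1 - u_S(3x_S^2 - 1) - \beta \end{pmatrix},$$

with non-converged starts discarded and roots merged when closer than
$10^{-5}$ (the cubic's roots are separated by more than 0.5 in the
parameter ranges used). Stability is classified from the eigenvalue
*moduli* of $J$ relative to 1 — the discrete-map criterion, not the sign
criterion of continuous flows: both moduli inside the unit circle is an
attractor, both outside a repeller, one each a saddle. A modulus within
$10^{-6}$ of 1 triggers a marginal-case warning. In one dimension,
`fixed_points_1d()` takes the real roots of $x^3 - x + k$ (via `polyroot`,
Newton-polished, and cross-checked in the tests against a bisection grid
scan) with stability from the drift derivative $1 - 3x^2$.

## Randomness and reproducibility

Trial $i$ of a batch with seed $s$ runs on its own RNG substream seeded by
a fixed integer mix of $(s, i)$, so batches are bitwise reproducible and a
single trial can be re-run in isolation. Sweeps derive each value's batch
seed from the *value*, not its position, making sweep rows invariant to the
order in which values are listed. Output files embed the full resolved
configuration (every numeric parameter plus seeds) as commented header
lines; the wall-clock timestamp goes to standard error only, so identical
invocations reproduce output files byte for byte.

## Decision-rule choices

Choices the model statement leaves open, fixed here once and documented:

* **Absolute-value stopping test.** An other-centric settle shows the sum
  rising to $+30$; egocentric trials must terminate symmetrically, which
  requires $|\sum x| \ge \theta$ with the sign giving the outcome, rather
  than a single signed bound.
* **Same-step double crossing.** The accumulator with the larger absolute
  sum wins; on an exact tie, the fast process. Deterministic, and
  vanishingly rare at the default noise level.
* **Non-decisions.** Trials that never cross within `max_steps` get
  outcome and winner `"none"` and are excluded from outcome proportions
  and decision-time statistics.

## What the simulations do and do not show

Everything in the test suite runs on data generated by the model itself —
the simulator *is* the study system, and the test conditions are the four
canonical regimes at their stated parameters. Batch sizes used by the
checks (50 for the unanimity regime, 500–2000 for proportion checks, 1000
for timing contrasts) are chosen so that binomial error bands are narrow
relative to the effects being asserted. Passing tests therefore show that
the implementation realises the model's claimed regime structure; they say
nothing about fit to empirical perspective-taking data (mouse-tracking or
otherwise), which this package does not attempt. Other known limitations:

* Within-trial tilt only: the across-trial drift of $k$ (incremental
  strategy strengthening) is deliberately not implemented; `k` is constant
  within and across trials.
* No continuous-time (SDE) reformulation or higher-order integrators; the
  model is the printed map.
* The trial-length cap and non-decision handling are artifact conventions;
  the model statement leaves trial length unbounded.
* Stability classification near the fold ($|k| \to 2/(3\sqrt3)$) and unit
  eigenvalue moduli are flagged, not resolved.
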