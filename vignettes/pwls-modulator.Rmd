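---
title: "Performance-weighted regression for velocity-controlled reflex walking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Performance-weighted regression for velocity-controlled reflex walking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwlsgait)
```

## The model and its assumptions

A reflex-based walking controller computes a stimulation signal for each
of eight muscles per leg (SOL, TA, GAS, VAS, HAM, RF, GLU, HFL) from
delayed sensory feedback, with the wiring switching between stance and
swing. Three primitive laws are combined:

* **force feedback** `u = G · F̃(t − Δt)` — the Golgi-tendon pathway,
  positive on the stance extensors (compliant leg behaviour, push-off);
* **length feedback** `u = max{0, G (l − l^tar)}` — the muscle-spindle
  stretch reflex, driving TA toe clearance and, in swing, the hip flexor
  (with hamstring stretch inhibiting it);
* **muscle-driven PD control**
  `u = max{0, K (θ^tar − θ) − D θ̇}` (or the sign-flipped form for
  antagonists) — torso balance in stance and limb placement before heel
  strike, where the SIMBICON law
  `θ_h^tar = θ_0 + c_d d + c_v v_x` sets the swing-hip target from the
  hip-to-ankle offset `d` and the horizontal velocity.

Stimulations are clamped to `[u_min, 1]` (`u_min = 0.01`), circuits of
the inactive phase contribute exactly zero, and all sensory channels are
read through a zero-order-hold delay buffer (defaults: 20 ms ankle,
10 ms knee, 5 ms hip pathway). Muscle activation follows first-order
excitation–activation dynamics `da/dt = (u − a)/τ(u, a)` with the
asymmetric time constant `τ = 0.01(0.5 + 1.5a)` s during activation and
`τ = 0.04/(0.5 + 1.5a)` s during deactivation, integrated by explicit
Euler at the 5 ms simulation step and clamped to `[0, 1]`. The actuator
force is Hill-type: `F = (a F_l F_v + F_p) F^0`, with per-muscle maximum
isometric forces (SOL 4000 N … HFL 2000 N) and an inelastic tendon.

**Adopted-form assumption.** The exact force–length, force–velocity and
passive curves of the source controller family are not public. The
package adopts the standard Geyer/Herr-style closed forms — a bell-shaped
`F_l` with maximum 1 at the rest length (width 0.56, edge residual 0.05),
a Hill `F_v` equal to 1 at zero velocity and 0 at the maximum shortening
speed (12 rest-lengths/s, curvature K = 5, eccentric plateau N = 1.5),
and a passive force that is zero at or below rest length and quadratic
above it. All constants live in `muscle_curve_constants()`. The metabolic
model (`metabolic_rate()`) follows the usual basal + activation heat +
maintenance heat + shortening heat + positive mechanical work structure
with constants in `metabolic_constants()`. Both are assumptions: tests
assert only their contract (bounds, monotonicity, additivity), not
specific magnitudes.

**The 56-parameter registry** (`parameter_registry()`) is an explicit
reconstruction: the published description names the circuits and five
specific parameters (`G_HFL`, `l_HFL_tar`, `G_HAM_HFL`, `l_HAM_HFL_tar`,
`theta_t_tar`) but not the full list. The registry covers the stance
force-feedback gains, the TA stretch reflex with SOL suppression,
torso-balance PD gains, late-stance and late-swing additions,
stance-preparation PD control with the SIMBICON coefficients,
per-muscle pre-stimulation offsets and four phase thresholds — exactly
56 named entries with feasible bounds. Datasets, modulators and the
CMA-ES search space all use this fixed order.

## The objective and dataset collection

A trial is scored by
`f = Σ_t (r_alive + r_forward + r_torso) + r_fall + α_E (CoT − 0.3)`,
with `r_alive = −1`, `r_forward = min(1, α_v |v_x − v^tar|²)`,
`r_torso = α_t θ_t²`, a 5000 penalty for falling within 700 steps, and
defaults `α_E = 5000`, `α_v = 5`, `α_t = 1`, a 5000-step (25 s) limit.
The printed description of the velocity penalty ("lower limit of −1")
conflicts with its formula (a `min(1, ·)` cap starting at 0); the formula
is implemented as printed and a `forward_shift` option subtracts 1 for
the `[−1, 0]` variant. CoT is undefined for zero-distance trials; those
receive a configurable cap (`cot_cap = 10`) so immediate falls stay
finite.

Collection (`velocity_sweep()`) runs two threads from identical initial
parameters: target velocities 1.3 → 2.0 m/s and 1.2 → 0.4 m/s in
0.1 m/s steps, `G = 300` CMA-ES generations of `λ = 20` candidates
(`μ = 7`, `σ⁰ = 0.1`) per velocity — 17 velocities × 300 × 20 = 102,000
trials at the defaults. On a velocity change the step size and both
evolution paths are reset while the mean and covariance carry over. Every
candidate whose trial survives to the step limit is admitted as a
`(v_x, Y, CoT)` record; the merged dataset is sorted by velocity. The
CMA-ES update rules are the standard rank-μ forms; only `λ`, `μ`, `σ⁰`
and `G` are problem-specific. Whether admission should consider all
candidates or only final-generation ones is ambiguous in the source
description; all candidates are admitted, which matches the reported
~50% admission fraction.

## PWLS

For each parameter the polynomial coefficients minimise
`E = ||β ⊗ (y − Vω)||²` with `β_j = A^((C̄oT_j − CoT_j)/C̄oT_j)` and
`C̄oT_j` the mean CoT over the window `[j − M, j + M]` (defaults
`M = 125`, window 251; the window shrinks at dataset edges — the source
does not state its edge policy). Numerical choices:

* the explicit normal-equations inverse is ill-conditioned at degree 6 on
  raw velocities, so the identical problem is solved by QR-based weighted
  least squares on a centred/scaled velocity basis, with coefficients
  transformed back to the raw power basis for serialisation; agreement
  with both the explicit normal equations and brute-force minimisation of
  `E` is asserted in the tests;
* weights are computed in log space and renormalised by their maximum
  (harmless by scale invariance), so `A` up to `1e200` stays finite;
* ties in `v_x` keep insertion order (stable sort);
* rank deficiency (fewer distinct velocities than `degree + 1`) raises a
  singular-fit error naming the offending parameter.

`fit_modulator()` runs 56 such fits sharing one weight vector and returns
the modulator; `modulate()` evaluates it at a target velocity, clamping
out-of-range targets to the fitted range and values to registry bounds
(both with warnings — the behaviour outside the fitted range is undefined
in the source, which stabilises walking at 1.25 m/s before applying
targets). Degree 6 is the default, the smallest degree found sufficient
in the source work; the examples below use lower degrees where the
dataset's velocity span is narrow.

## Efficiency analysis

`fit_cot_curve()` fits `CoT(v) = c2 v² + c1 v + c0` by ordinary least
squares; `integrate_cot()` evaluates its exact antiderivative between
velocity limits. A worked check: for the curve `0.6v² − 1.2v − 0.1` over
[0.7, 1.6] m/s direct quadrature gives

```{r}
integrate_cot(c(-0.1, -1.2, 0.6), 0.7, 1.6)
```

(a negative CoT curve is of course unphysical — this particular
polynomial is useful only as an integration check; note the test suite
verifies the same value by adaptive numerical quadrature).
`substitution_experiment()` replaces named parameter groups of a baseline
modulator with a donor's polynomials, applies the steady-walking gate
(> 30 m without a fall) and the tracking exclusion rule (achieved speed
within 0.05 m/s of target), fits CoT curves on the survivors and
integrates all conditions over the intersection of their surviving
velocity ranges, so every comparison uses identical limits. Replicates
are seed-controlled; results are means over replicates.

## The surrogate evaluator

The surrogate (`surrogate_config()`, `surrogate_evaluate()`) is *not* a
physics model. It encodes exactly the structure the method exploits:

* a ground-truth optimal parameter set `y*(v)` per velocity (quadratic
  curves centred on registry defaults, fixed by the config seed);
* achieved velocity = target + a signed projection of the parameter
  deviation (gain 2.0) + Gaussian noise (sd 0.02 m/s);
* CoT = `0.4 v² − 0.96 v + 0.876` (minimum 0.3 at 1.2 m/s, inside the
  plausible human band) + `3.0 · d²` for RMS parameter deviation `d` +
  observation noise (sd 0.002);
* a fall whenever `d` exceeds the stability radius 0.8, plus a baseline
  fall probability 0.45 so that roughly half of optimisation trials are
  admitted, matching the reported collection yield.

The CoT observation noise is deliberately small relative to the
deviation penalty at converged CMA-ES step sizes: if noise dominates, the
performance weights amplify noise-lucky records and the efficiency
gradient the method is supposed to recover disappears. Trials are
deterministic given their seed and do not disturb the caller's random
stream.

What passing tests on the surrogate do **not** show: anything about
contact dynamics, ground reaction forces, kinematic similarity to human
walking, absolute CoT magnitudes, or which circuits matter in a real
musculoskeletal simulation. They show that the pipeline — collection,
weighting, regression, modulation, integration, substitution — correctly
recovers structure that is present in the data by construction.

## Problem sizes and reproducibility

The default test and acceptance runs use a reduced collection (3 target
velocities, 30 generations, 10 candidates — 900 trials), degree-2
modulators over the resulting ~0.35 m/s velocity span, 7-point evaluation
grids with 3 replicates, and 50 s evaluation trials so the 30 m
steady-walking gate is reachable at low speeds. These sizes were chosen
so a full pipeline run completes in seconds while still exercising every
stage; the full 102,000-trial schedule is enumerated exactly but not
executed. All stochastic steps take explicit integer seeds.

## Known limitations

* The registry, muscle curves and metabolic constants are reconstructions
  of unpublished material; quantitative muscle-level outputs should not
  be compared against published traces.
* The controller is not closed through a physics engine here: joint
  torques, contact and falls are only represented through the evaluator
  contract. An adapter supplying a real `(Y, v_tar, seed) → trial_trace`
  evaluator can replace the surrogate without touching the rest of the
  pipeline.
* PWLS is unregularised by design; with very small datasets and high
  degree it inherits ordinary least squares' variance. Degree selection
  is fixed, not cross-validated.
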