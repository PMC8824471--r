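---
title: "A nine-state Markov model of Nav channel gating with parallel fast and slow inactivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A nine-state Markov model of Nav channel gating with parallel fast and slow inactivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resurgenav)
```

## The model

Voltage-gated sodium (Nav) channels in cerebellar Purkinje neurons produce
three kinetically distinct current components: a fast transient current
(I~NaT~) on depolarization, a small non-inactivating persistent current
(I~NaP~), and a resurgent current (I~NaR~) — a slowly rising and slowly
decaying inward current revealed on repolarization after a brief
depolarization. `resurgenav` implements a continuous-time Markov scheme in
which all three components arise from one channel population with two
*parallel* inactivation pathways:

* an activation chain `C1 - C2 - C3 - O` (forward rates `a11, a12, a13`,
  backward `b11, b12, b13`);
* a fast-inactivation pathway: `O - IF1` (`a2`/`b2`) with a deeper state
  `IF1 - IF2` (`a6`/`b6`), plus a ladder of closed-inactivated states
  `IC1 - IC2 - IF1` that reuses the activation-chain horizontal rates and
  connects vertically to `C1/C2/C3` through `a3` (recovery) and `b3`
  (closed-state inactivation);
* a slow-inactivation pathway: `O - IS` (`a2s`/`b2s`) with a return route
  `IS - C3` (`a3s`/`b3s`).

Only `O` conducts. I~NaT~ decay corresponds to occupancy draining from `O`
into `IF1`/`IF2`; I~NaR~ corresponds to `IF1` re-opening through `O` on
repolarization; I~NaR~ decay and the duration-dependent attenuation of its
peak correspond to the slow, quasi-absorbing accumulation of occupancy in
`IS`.

Each free rate is a single exponential in voltage, e.g.
`a3 = Tf * a3_variable1 * exp(-V / a3_variable2)`, with 24 free parameters
in total (`nav_param_names()`), and `Tf = 1 / Q10^((37 - T_C) / 10)` scaling
all rates from 37&nbsp;°C to the working temperature (defaults `Q10 = 3`,
`T = 295 K`, giving `Tf = 0.192`).

Two rates are never free. Microscopic reversibility around the two
triangles that share the `C3 - O` edge fixes

```
b2  = (a13 * a2  * a3 ) / (b13 * b3 )     # C3 - O - IF1 cycle
b3s = (a2s * a3s * a13) / (b2s * b13)     # C3 - O - IS  cycle
```

and these two constraint equations are what pins the topology: the
arrangement above is the only placement of the rate pairs for which they
are the detailed-balance solutions of the cycles they close.
`cycle_balance_residuals()` verifies both identities at any voltage. All
other cycles (the closed/closed-inactivated rectangles) balance
automatically because they reuse the same horizontal and vertical rate
pairs.

Two optimized parameter tables ship with the package: `nav_parameters("WT")`
(wild type) and `nav_parameters("Scn4b-/-")` (a refit describing Purkinje
neurons lacking the Navβ4 accessory subunit), also available as plain-text
files under `inst/extdata/`.

## Units

Voltages are millivolts, times milliseconds, rates 1/ms. The package makes
this convention explicit rather than configurable; all shipped quantities
(time constants in ms, voltages in mV, currents in units of
`g_max * mV` with `g_max = 1`) follow from it. Current uses the ohmic form
`I = g_max * P_open * (V - E_rev)`; every summary statistic the package
reports is a ratio, a time constant or an argmax voltage, so the arbitrary
conductance scale cancels. The default reversal potential `E_rev = +75 mV`
corresponds through the Nernst relation to 151 mM external / 8 mM internal
sodium at 295 K (`nernst_potential(151, 8)` = +74.7 mV); the low-sodium
condition (50/15 mM, about +30 mV) is available by passing a different
`e_rev_mV`.

## Numerics

**Propagation.** Occupancies evolve as `p(t + dt) = p(t) %*% expm(Q(V) dt)`.
The matrix exponential (dense Padé scaling-and-squaring, via compiled code)
is exact for piecewise-constant voltage, so the sampling interval only
controls where the trajectory is *observed*, not its accuracy. The default
sampling interval is 0.005 ms; halving it changes measured peaks by well
under 0.1% (this is tested). The generator is stiff — rates span ~1e-4 to
~1.6e4 / ms at −90 mV — which is precisely why matrix exponentials are used
instead of explicit time stepping; an explicit-Euler/RK4 cross-check at
dt = 1e-4 ms agrees to 1e-6 where those methods are stable.

**Ramps** are discretized into piecewise-constant sub-steps of at most
0.25 mV (about 2.1 ms per sub-step at the standard 0.12 mV/ms speed);
halving the discretization changes ramp peaks by <0.5% (tested).

**Steady states** solve `p Q = 0, sum(p) = 1` by a least-squares null-space
solve of the transposed generator, falling back to a 1e6-ms exponential jump
if the solve is ill-conditioned. Entries below zero by rounding are clipped
and the vector renormalized.

**Measurement conventions.** Peaks are signed extrema of the current; the
persistent level is the mean over the trailing 5% of a segment and is
subtracted before resurgent peaks or decay constants are measured
(subtraction is idempotent). The "1/e" decay time is the exact interpolated
crossing of `|I_peak|/e` (1/e retention is 63.2% decay; descriptions of this
convention as "64%" are a rounding). Single-exponential and Boltzmann fits
use Levenberg–Marquardt least squares with deterministic initialization
(`A = y[1] − C`, `C = y[n]`, `tau = range(x)/3`; Boltzmann `V_h` from the
half-maximal point, `|k| = 6 mV` with the sign from the curve direction), so
every fit is bit-reproducible. Both Boltzmann conventions in circulation
differ in whether the slope divides the exponent; the package implements
`1/(1 + exp((V_h − V)/k))`, the form in which `k` has millivolt units.

## The protocol library

`run_protocol()` exposes the nine standard optimization protocols
(`availability`, `activation`, `tau_inact`, `recovery`, `persistent`,
`inar_ratio`, `duration`, `inar_tau`, `prepulse`), and dedicated functions
implement the figure-level paradigms (voltage dependence of I~NaR~,
sequential recovery, envelope test, slow ramps). Grids that the protocol
definitions state (e.g. availability conditioning −120..−10 mV; activation
−77..0 mV in 3 mV steps; prepulse durations 2–36 ms) are defaults; where a
definition leaves an increment or window open the package fixes one and
verifies convergence:

* availability conditioning increment 5 mV; test step 20 ms;
* recovery intervals 0.5–500 ms (log-ish spacing), conditioning pulse 20 ms;
* resurgent measurement window 100 ms (long enough for peak and decay at
  every tested repolarization voltage);
* duration-dependence increment 2 ms.

```{r duration, eval = FALSE}
wt <- nav_parameters("WT")
dc <- duration_dependence(wt)
fit_single_exponential(dc$x, dc$y)
autoplot(dc)
```

## Fitting

`synthesize_targets()` runs all nine protocols and (optionally) adds i.i.d.
Gaussian noise with a fixed seed, producing reproducible targets for
parameter-recovery experiments. `fit_parameters()` minimizes the summed
squared differences between simulated and target curves with a Nelder–Mead
simplex run in log-parameter space, which enforces rate positivity without
penalty terms. Default convergence tolerances are 0.01 (absolute) for both
the simplex cost spread and the parameter spread, with a configurable
evaluation cap; exceeding the cap reports `converged = FALSE` rather than
failing. Per-protocol weights default to 1 but are exposed because the
curves differ in length and scale — time-constant curves are measured in
tens of ms while amplitude ratios are ≤ 0.25, so scale-normalized weights
(`1/max|y|^2`) are the appropriate choice when curve-space recovery across
*all* protocols is the goal, and that is what the recovery experiments in
the test suite use.

The prepulse protocol is special: its published purpose is to make the peak
resurgent current *constant across prepulse voltages* without prescribing
its magnitude. With a target curve supplied, its cost is an ordinary sum of
squared differences (so self-consistency costs are exactly zero); with
`target = NULL` it is the dispersion of the simulated peaks around their
mean, the magnitude-free form.

`refit_scn4b()` reproduces the variant-fitting procedure: restart from the
wild-type rates with only the resurgent-to-transient ratio protocol
retargeted, all other protocols held at the wild-type model's own curves.

**What the synthetic targets do and do not emulate.** They are noiseless or
i.i.d.-noisy versions of the model's own summary curves. They do not emulate
cell-to-cell variability, correlated residuals, series-resistance or
space-clamp artifacts, or liquid-junction offsets; passing recovery tests
therefore demonstrates that the optimizer can navigate the model's cost
landscape, not that the model is identifiable from real recordings. Because
many parameter sets produce nearly identical curves, recovery is asserted in
curve space, never in parameter space.

## Behavior of the shipped parameter tables

All quantitative statements below are computed by the test suite or the
acceptance script; they document what the shipped tables produce.

* The peak resurgent current is maximal at a repolarization potential of
  −45 mV, it is independent of the prepulse potential (coefficient of
  variation ~1.1% across −35..−5 mV prepulses), and recovery of the
  transient current at −90 mV is essentially complete within 20 ms.
* The resurgent current rises and decays 1–2 orders of magnitude more
  slowly than the transient current, and its decay reflects accumulation in
  `IS`; with the Scn4b-null table, occupancy shifts from `IF2` toward `IS`
  and the resurgent amplitude falls to ~73% of wild type (~63% when both
  are first normalized to their transient peaks) while the decay time
  constant changes by only ~10%.
* The duration-dependent attenuation of the peak resurgent current fits a
  single exponential with a time constant of ~43.5 ms after +20 mV
  prepulses. Entry into `IS` is noticeably voltage dependent at depolarized
  potentials (the equivalent constant is ~12 ms for 0 mV prepulses), which
  also causes the repetitive-repolarization envelope to deviate from the
  sustained-repolarization trace by several tens of percent late in the
  train. These two behaviors are properties of the shipped rate tables
  under the documented assembly; the test suite asserts the measured
  values and shapes rather than idealized voltage independence.
* The steady-state availability curve is not perfectly monotone: the model
  produces a small window-current bump near −75 mV (normalized availability
  ~1.02) before the main Boltzmann-like decline (V½ ≈ −63 mV). Tests assert
  monotonicity only over the falling limb.

## Known limitations

* **Single population.** The model deliberately describes one channel
  population generating all three current components; it therefore cannot
  produce differential recovery of the transient and resurgent components
  after brief gaps — `sequential_recovery()` returns approximately equal
  ratios by construction.
* **Identifiability.** Many topologies and parameter sets fit the same
  curve families; no uniqueness claim is made, and no global optimization
  or identifiability analysis is provided.
* **Open-channel-block comparison.** `ob_scheme()` ships the 13-state
  competing topology (block state isolated on the open state) with
  structural invariants enforced, but its published rate constants are not
  included; `ob_placeholder_rates()` is an invented qualitative set, good
  only for the mechanism-contrast demonstration in
  `discriminate_mechanism()` (strong vs negligible duration-dependent
  attenuation, renewed transients on re-depolarization).
* **No recording artifacts.** Series resistance, capacitive transients,
  space-clamp error and channel noise are out of scope; simulated traces
  are ideal voltage clamp.
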