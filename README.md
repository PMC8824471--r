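# resurgenav

Markov kinetic modelling of the resurgent sodium current in cerebellar
Purkinje neurons: a voltage-clamp simulator plus rate-constant fitting
toolkit for a nine-state Nav channel gating scheme with *parallel* fast and
slow inactivation pathways.

Purkinje-neuron Nav channels generate three current components — the fast
transient current (I<sub>NaT</sub>) on depolarization, a small persistent
current (I<sub>NaP</sub>), and the resurgent current (I<sub>NaR</sub>), a
slow inward current revealed on repolarization after brief depolarizations.
The package is for electrophysiologists and modellers who want to simulate
these components under arbitrary step/ramp protocols, reproduce the standard
measurement conventions, and fit or perturb the underlying rate constants.

## The model

Nine states: closed `C1, C2, C3`; open `O`; closed-inactivated `IC1, IC2`;
fast-inactivated `IF1, IF2`; slow-inactivated `IS`.

```
IC1 == IC2 == IF1 == IF2            (a11/b11, a12/b12 horizontals; a6/b6)
 ||     ||     ||   /
 C1 === C2 === C3 = O               (a11/b11, a12/b12, a13/b13)
 (a3/b3 verticals)   \\ a2/b2
               C3 === IS === O      (b3s/a3s and a2s/b2s: slow pathway)
```

Occupancies evolve as `p(t+dt) = p(t) · exp(Q(V)·dt)` with the generator
`Q(V)` assembled from 16 voltage-dependent rates (units 1/ms, voltages mV);
of these, 14 derive from 24 free parameters via single-exponential voltage
laws scaled by a Q10 temperature factor, and two are fixed by microscopic
reversibility around the cycles through the `C3–O` edge:

```
b2  = (a13·a2·a3)  / (b13·b3)
b3s = (a2s·a3s·a13)/ (b2s·b13)
```

Current is ohmic, `I = g_max · P_O · (V − E_rev)`, with `E_rev = +75 mV`
(the Nernst potential for 151/8 mM Na⁺ at 295 K). Only ratios, time
constants and argmax voltages are reported, so `g_max` cancels.

Two optimized parameter tables ship with the package: wild type (`"WT"`)
and a Navβ4-null variant (`"Scn4b-/-"`).

## Worked example

```r
library(resurgenav)
wt <- nav_parameters("WT")

# duration dependence of the peak resurgent current:
# hold -90 mV, prepulse +20 mV (2..36 ms), repolarize to -45 mV
dc <- duration_dependence(wt)
head(round(dc$y, 4), 6)
#> [1] 1.0000 0.9494 0.9012 0.8551 0.8110 0.7689
fit_single_exponential(dc$x, dc$y)
#> <nav_exp_fit> A = 1.1787  tau = 43.529 ms  C = -0.12576  SSE = 7.759e-05

# voltage of maximal resurgent current (hold -80, 5 ms at 0 mV,
# repolarizations -70..-10 mV)
rv <- resurgent_voltage_curve(wt)
attr(rv, "v_max_mV")
#> [1] -45

# prepulse-voltage independence of the peak resurgent current
prepulse_peak_spread(wt)$cv
#> [1] 0.01082022

# reversal potentials for the two recording solutions
nernst_potential(151, 8); nernst_potential(50, 15)
#> [1] 74.68318
#> [1] 30.60635
```

The normalized peak resurgent amplitude falls strictly with prepulse
duration (time constant ≈ 43.5 ms for +20 mV prepulses), is maximal at a
repolarization potential of −45 mV, and is essentially independent of the
prepulse voltage (CV ≈ 1%). `autoplot()` methods draw traces, summary
curves and fits; `plot_occupancies()` shows how depolarization drives
occupancy into `IF1/IF2` and then slowly into `IS`, the mechanism behind
resurgent-current decay.

A command-line front end for simulation, protocol summaries and fitting is
included at `inst/cli/navclamp.R` (subcommands `simulate`, `protocol`,
`fit`, `compare`).

See the vignette (`vignettes/nav-gating-model.Rmd`) for the full model
description, numerical choices and known limitations.

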