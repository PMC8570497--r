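---
title: "Ephaptic coupling through the synaptic cleft: models, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ephaptic coupling through the synaptic cleft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prespike)
```

## The problem

At a giant synapse such as the calyx of Held, the presynaptic terminal and
its target cell enclose a cleft only tens of nanometres high. Membrane
currents generated during a presynaptic action potential (AP) must leave
this cleft either through its leak conductance to the interstitial space,
`g_cl`, or through the membranes that bound it. The resulting cleft
potential `v_cl` couples the two cells ephaptically: in the postsynaptic
cell the presynaptic AP appears as a small biphasic signal, the *prespike*.
This package implements a quantitative account of that coupling — a lumped
circuit with closed-form limiting regimes, an ODE model with voltage-gated
channels whose gating feeds back on `v_cl`, analytic cleft-geometry
relations, and an estimation pipeline that turns recorded prespikes into
estimates of the cleft time constant `tau_cl = c_cl / g_cl`, the cleft
conductance `g_cl`, the cleft-facing capacitance `c_cl` and the
extracellular resistivity `R_ex`.

## The lumped circuit and its two regimes

The cleft is a single electrical node. Currents entering it are the
presynaptic capacitive current plus any cleft-facing channel currents,
`i_enter = c_pre dv_pre/dt + sum(i_ion)`. Currents leave through `g_cl` and
through the membrane capacitances, giving

```
v_cl (g_cl + sum g_ion) + (c_pre + c_syn) dv_cl/dt = i_enter .
```

Two limits bracket the behaviour:

* **capacitive dissipation** (poorly conductive cleft): `v_cl` is the
  scaled integral of `i_enter`, and the voltage-clamp (VC) prespike is
  `-c_syn/(c_pre + c_syn) * i_enter` — for the symmetric calyx-type cleft
  (`c_pre = c_syn = c_cl`) exactly half the entering current, inverted, so
  the prespike resembles the inverted *first* derivative of the AP;
* **resistive dissipation** (well-conductive cleft): `v_cl = i_enter/g_cl`
  and the VC prespike is `-g_cl tau_cl^2 d2v_pre/dt2`, the inverted
  *second* derivative of the AP.

`predict_cleft_potential()` also exposes the full first-order solution
(scenario `"full"`), which converges to each closed form as `g_cl` goes to
its limit; a property test sweeps four decades of `g_cl` to confirm the
bracketing. Which derivative the measured prespike resembles is therefore a
regime diagnostic, implemented in `fit_derivative_models()` and
`compare_derivative_models()` as ordinary least squares of prespike peak
amplitudes on AP-derivative peak amplitudes with Pearson's r, the absolute
intercept ("deviation at origin") and paired t contrasts across trains.

A presynaptic calcium current in the cleft adds a *calcium prespike*:
`-i_ca` in the capacitive regime, `-tau_cl di_ca/dt` in the resistive one.
For a Gaussian `i_ca` of width `tau_ca`, the resistive calcium prespike is
biphasic with peaks at `t_peak ± tau_ca` and a positive peak equal to
`tau_cl/tau_ca * exp(-0.5)` times the current amplitude. Both `tau_cl`
estimators invert this relation:

* `estimate_tau_cl_peak_ratio()` reads `tau_ca` off the peak-to-peak delay
  (half of it) and scales the peak ratio by `exp(0.5)`;
* `estimate_tau_cl_slope()` regresses the calcium prespike on
  `-di_ca/dt`, allowing a small time shift found by an integer-sample lag
  scan with parabolic refinement; the slope is `tau_cl`.

With `tau_cl` in hand, the capacitive-prespike relation
`-i_post = g_cl tau_cl^2 v_pre''` yields `g_cl = |slope| / tau_cl^2`,
`c_cl = g_cl tau_cl`, and the disc-cleft relation `g_cl = 8 pi h / R_ex`
yields the resistivity (`derive_cleft_parameters()`).

## The ODE model with channel feedback

`simulate_synapse()` integrates the coupled pair

```
c_post dv_post/dt = c_cl dv_cl/dt - g_post (v_post - v_rest)
2 c_cl dv_cl/dt   = c_cl (dv_pre/dt + dv_post/dt) - g_cl v_cl
                    + sum g_max p_open (v_pre - v_cl - v_rev)
```

together with the master equations of Markov channel schemes: a five-state
sodium channel (C1–C2–C3–O–I), six-state high- and low-threshold potassium
channels (C1..C5–O) and a two-state calcium channel whose open probability
is squared. Every transition rate follows `k = a e^{b v}` with the
channel-specific constants shipped in the package and, crucially, `v` is
the potential the cleft-facing channel actually senses, `v_pre - v_cl`: the
cleft potential feeds back on gating. The two derivative equations
reference each other; because they are linear in the derivatives they are
solved by exact algebraic elimination at each step rather than iteration.
`g_cl = Inf` encodes a zero-resistance cleft (`v_cl ≡ 0`), the reference
condition for quantifying feedback effects.

Numerical choices:

* **Solver.** The closed-state sodium transitions reach ~1.2e7/s near rest,
  which makes the system stiff: an explicit embedded Runge–Kutta pair is
  forced to ~100 ns steps and needs minutes for a 5 ms train. The default
  integrator is therefore `deSolve`'s `lsoda` (stiff-capable) at
  `atol = 1e-9`, `rtol = 1e-8`; `"ode45"` remains available, and a test
  confirms the two agree to better than 1e-4 relative on the cleft
  potential.
* **Input interpolation.** `v_pre` and its derivative are supplied by a
  cubic spline so adaptive steps can fall between samples; inputs should be
  sampled at 5 µs or finer.
* **Conservation as a check.** Occupancies are integrated raw and only
  renormalised for reporting, so the `|sum - 1| < 1e-6` test is a genuine
  accuracy check, not an enforced identity.
* **Sign conventions.** Inward currents are negative; `v_cl` is relative to
  the grounded interstitial space; the reported `i_rec` is the current a
  postsynaptic voltage-clamp amplifier would record (`-c_cl dv_cl/dt`,
  negative first peak for a rising AP).

The slow/fast AP comparison (`simulate_ap_grid()`) runs a calcium-only
model (densities for the other conductances set to zero) at a grid of cleft
leak resistances and summarises `v_cl` extrema and the delay and reduction
of the calcium current relative to the zero-resistance reference. Because
the published AP template is not public, the calcium conductance density is
*calibrated at run time* so the zero-resistance current peaks at 2 nA —
`calibrate_ca_density()` is exact in one pass since without feedback the
peak is strictly proportional to density.

## Cleft geometry

For a radially symmetric (disc) synapse with homogeneously distributed
capacitive current density, the radial field grows linearly from the
centre and the potential profile is
`v(x) = (r^2 - x^2) R_ex C_m/(4h) dv_pre/dt`; a sheet-like finger uses
`(2h)^{-1}` because its escape path is more restricted. Integrating the
postsynaptic capacitive current density gives the VC prespike
`pi r^4 R_ex C_m^2/(8h) v''` for the disc — fourth-power scaling in the
radius, which is why intracellular prespikes are a giant-synapse
phenomenon — and `A r^2 R_ex C_m^2/(3h) v''` for sheets of total area `A`.
The disc cleft conductance `g_cl = 8 pi h / R_ex` is radius-invariant:
doubling `r` doubles both the current-generating area and the escape
perimeter. Fenestration of a 1000 µm² disc into 4 µm fingers leaves ~2.5%
of the centre potential and ~3.3% of the prespike (`fenestration_ratios()`,
computed from the underlying profile and prespike functions, not from
memorised constants; the sheet integral is cross-checked against numeric
quadrature in the tests).

Everything internal is SI; the field's conventional units (Ω cm, nm, µm,
µF/cm², nS, pA) enter and leave through explicit converters (`ohm_cm()`, `nm()`,
`um2()`, `to_nS()`, ...) because silent 10²–10⁴ unit slips are the main
implementation hazard in these formulas.

## The synthetic-recording generator

No raw recordings are distributed with the package, so the generator
(`synthesize_paired_recording()`, `synthesize_p5_recording()`) emulates the
study protocol with known ground truth:

* an **AP surrogate** built as the product of two logistic ramps with
  independent rise and decay time constants, rescaled in time to an exact
  requested FWHM and in amplitude to an exact peak. Defaults: rest -80 mV,
  amplitude 120 mV, FWHM 0.5 ms (juvenile), rise/decay ratio 0.5. The
  amplitude is a documented guess — the simulations report their
  sensitivity to it over 100–140 mV;
* **APW trains** of 45 identical commands at 100 Hz (the voltage-clamp
  protocol), or decaying/broadening trains (geometric per-stimulus factors)
  emulating natural high-frequency trains in which the AP becomes smaller
  and slower — the amplitude spread these trains provide is what makes the
  peak regressions identifiable;
* a **Gaussian calcium current** per stimulus during AP repolarisation
  (default peak -1.9 nA, `tau_ca` 0.217 ms, i.e. FWHM 0.51 ms);
* the **P/5 protocol**: passive sweeps driven by `v_pre` scaled by exactly
  1/5 about rest, which is too small to open calcium channels, so
  `mean(active) - 5 mean(passive)` removes the capacitive prespike. Epoch
  folding skips the first 20 stimuli and averages the next 25 by default
  (EPSC contamination is worst early in a real train);
* additive i.i.d. Gaussian noise on currents only (default 10 pA per
  sweep), and an optional EPSC contaminant as a difference of exponentials
  (0.2 ms rise, 1 ms decay) after each calcium-current trough.

What the generator does **not** emulate — and what green tests therefore do
not demonstrate about real data: series-resistance filtering of the
prespike, correlated (1/f or line) noise, stochastic channel gating,
vesicle release and true EPSC kinetics, drift between active and passive
sweeps, and any deviation of the real AP from the logistic-product shape.

## Decisions on genuinely open points

* **Recovery conditions.** The parameter-recovery property uses 20 seeded
  recordings spanning `tau_cl` 3–30 µs at `c_cl` 10 pF, with per-sweep
  noise set so the epoch-averaged calcium prespike has SNR 10
  (`noise_sd = peak/10 * sqrt(use/6)`; the factor 6/use is the variance of
  `mean(active) - 5 mean(passive)` after folding). The slope method's
  median relative error is held under 10%, and the two estimators' median
  disagreement under 30% — "comparable", as the two published point
  estimates (5.7 and 9 µs) indeed differ by about a third.
* **Delay measure.** The slow-AP simulation's published "45 µs delay in the
  onset" of the calcium current is ambiguous (onset threshold? peak?). The
  package computes both: onset as the first crossing of 10% of the peak,
  and the peak-time shift with parabolic refinement. The grid reports both
  columns; the headline delay uses the peak shift, the same measure as the
  fast-AP value, and the published text itself equates the delay with the
  shift of the `v_pre - v_cl` maximum, a peak measure.
* **Cleft fraction.** Immunolabeling places a fraction of the calcium
  channels outside the cleft; the default assumes 2/3 of the measured
  current is cleft-facing (estimates scale by 1/fraction), with 1.0
  available as the lower bound.
* **`g_cl` for the slow/fast comparison.** 0.67 µS (≈1.5 MΩ), the in-text
  value; the grid runner also accepts the 0/1/5 MΩ set.
* **Derivative estimation.** Savitzky–Golay local quadratics (default
  7-sample window): raw differences amplify recording noise unacceptably at
  50–200 kHz. The window trades noise for attenuation of the narrow
  second-derivative lobes (a few percent at recording rates); tests that
  need sub-percent derivative accuracy use a 5-sample window or finer
  sampling.
* **Peak picking.** Biphasic peak extraction takes the largest qualifying
  extremum before the first opposite-sign peak, then the largest opposite
  extremum after it, with a prominence threshold of four noise scales
  floored at a quarter of the dominant deflection, and parabolic
  sub-sample refinement. Degenerate inputs fail loudly ("no prespike
  detected"); single-AP regressions are flagged under-determined; paired
  comparisons of identical fit lists return t = 0, p = 1 rather than
  erroring on zero variance.
* **`g_cl` from a single APW train.** With identical commands the per-AP
  peak regression is degenerate, so the pipeline obtains
  `g_cl tau_cl^2` by regressing the upscaled passive epoch (the capacitive
  prespike) on the command's second derivative *across time samples*; the
  peak-based regression remains available for decaying trains.

## Problem sizes

The shipped tests and the acceptance script use: 200 kHz simulation
sampling (500 kHz for the fast AP), 50 kHz recording-grade sampling,
45-stimulus trains for the study protocol and 8–12-stimulus trains for unit
properties, 20 recordings for the recovery sweep and 100 seeded batches per
regime for the discrimination property. The full suite runs in well under
five minutes on a single core.

## Known limitations

The cleft is lumped into one node in the ODE model (spatial structure lives
only in the analytic geometry module); channel kinetics carry no
temperature scaling; the postsynaptic cell is passive; the closed-form
prespike predictions assume the postsynaptic side is voltage-clamped, so
`g_syn` and the non-cleft-facing postsynaptic parameters enter only the
current-clamp low-pass (`cc_prespike_from_current()`). Quantities derived
from the slow/fast AP simulations inherit the surrogate-AP assumption and
should be read with the reported amplitude-sensitivity alongside.
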