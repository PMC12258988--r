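---
title: "A conductance-based model of spinal motoneuron bistability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based model of spinal motoneuron bistability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnbistab)
```

## The model

`mnbistab` implements a single-compartment Hodgkin–Huxley-type model of a
spinal motoneuron. The membrane potential obeys the current balance

$$C\,\frac{dV}{dt} = -I_{NaF} - I_{NaP} - I_{Kdr} - I_{Kv1.2} - I_{CaL}
  - I_{KCa} - I_{CAN} - I_L + I_{inj},$$

with capacitance $C = 1\,\mu F/cm^2$ and all currents in $\mu A/cm^2$
(outward positive). The spike-generating pair is a fast sodium current
($I_{NaF}$, instantaneous cubic activation, dynamic inactivation) and a
delayed-rectifier potassium current ($I_{Kdr}$, fourth-power activation).
Four modulatory currents default to zero conductance and are switched on per
experiment: a persistent sodium current ($I_{NaP}$, instantaneous,
non-inactivating), a slowly inactivating Kv1.2-type potassium current, a
calcium-activated non-specific cation current ($I_{CAN}$, TRPM5-like) and a
calcium-dependent potassium current ($I_{KCa}$, SK-like). A high-voltage
activated L-type calcium current ($I_{CaL}$) and an ohmic leak complete the
set. Every gate follows first-order kinetics
$\tau_x(V)\,dx/dt = x_\infty(V) - x$ with Boltzmann steady states;
`steady_state()` and `time_constant()` expose the curves.

Potassium currents share a Nernstian reversal
$E_K = 26.54\,\mathrm{mV}\cdot\ln([K^+]_o/[K^+]_i)$ (natural logarithm — the
only reading consistent with the printed 26.54 mV coefficient), so the
extracellular potassium concentration `K_out` is a physiological control
parameter.

Intracellular calcium (mM, in a thin sub-membrane shell) follows

$$\frac{d\,Ca}{dt} = -f\,\alpha\,I_{CaL} + k_{CICR}\,Ca - Ca/\tau_{Ca},$$

where $f = 0.01$ is the unbound fraction, $\alpha = (2F\delta)^{-1} =
5\times10^{-4}\,\mathrm{mM\,cm^2\,ms^{-1}\,\mu A^{-1}}$ converts current
density to concentration rate ($\delta = 0.1\,\mu m$ shell), and the pump
clears with $\tau_{Ca} = 10$ ms. Calcium-induced calcium release (CICR) feeds
back linearly with gain $k_{CICR} = 0.096\,\mathrm{ms^{-1}}$, extending the
effective clearance constant to
$\tau_{eff} = (1/\tau_{Ca} - k_{CICR})^{-1} = 250$ ms (`effective_tau()`).
Gains at or above $1/\tau_{Ca}$ would make calcium grow without bound, so the
constructor rejects them. Both Ca-dependent currents saturate with Michaelis
factors $Ca/(Ca + K)$, with $K_{CAN} = 0.74\,\mu M$ and $K_d = 0.2\,\mu M$.

The bistability mechanism under study is a positive feedback loop: spikes
open L-type channels, CICR amplifies the calcium transient, calcium activates
the depolarizing $I_{CAN}$, which sustains firing and further calcium entry.
$I_{KCa}$ opposes the loop; $I_{NaP}$ and elevated $[K^+]_o$ facilitate it.

## Fixed modelling choices

* Unit system mV–ms–µA/cm²–mS/cm²–µF/cm²–mM throughout, no internal
  conversions.
* $E_{Ca}$ is held at the constant 80 mV (not Nernst-updated with the shell
  concentration).
* $m_{NaF}$ and $m_{NaP}$ are algebraic functions of $V$ (instantaneous
  activation); the persistent sodium current does not inactivate
  ($h_{NaP}\equiv 1$ is eliminated). The state vector therefore has exactly
  eight components: $V$, $h_{NaF}$, $m_{Kdr}$, $m_{Kv1.2}$, $h_{Kv1.2}$,
  $m_{CaL}$, $h_{CaL}$, $Ca$.
* Calcium is floored at zero after each accepted solver step; equation (2)
  can undershoot transiently at machine precision.
* The documented operating ranges $g_{Kv1.2}\in[0,10]$ mS/cm² and
  $[K^+]_o\in[4,12]$ mM are enforced as validation *warnings*, not errors, so
  parameter sweeps may probe their edges.

## Numerical integration

The full system is integrated by an adaptive Dormand–Prince 5(4) embedded
Runge–Kutta pair implemented in C++, with the standard fifth-order continuous
(dense-output) extension. Defaults: relative tolerance $10^{-8}$, absolute
$10^{-10}$, dense sampling every 0.05 ms (about 20 samples per millisecond,
enough to resolve the 1–2 ms action potentials). Injected-current programs
are piecewise linear; integration steps never straddle a segment boundary, so
discontinuous steps are handled exactly and the first-same-as-last stage is
re-seeded after each jump. Spike times are detected on the dense solution
(0.05 ms scan) as upward crossings of −10 mV — the model's action potentials
overshoot 0 mV while plateaus stay well below — reported at the spike peak,
with a 2 ms refractory guard. There is no randomness anywhere: identical
inputs give bitwise-identical traces.

The test suite cross-checks the integrator against `deSolve::ode45` driving
the package's R-level right-hand side over a spiking segment (agreement to
better than $10^{-3}$ mV) and against closed forms for the passive membrane
and the clamped calcium equation.

## Protocols and threshold detection

`make_ramp()` builds the symmetric triangular ramp used to detect
bistability: the onset threshold `I_up` is the injected current at the first
ascending-phase spike, the offset threshold `I_down` the current at the last
descending-phase spike, and hysteresis `delta_I = I_up - I_down > 0`
indicates coexisting silent and spiking states. Because both thresholds creep
as the ramp slows, `measure_hysteresis()` doubles the phase duration
(default start 5 s, cap 80 s) until both move by less than 0.02 µA/cm²; the
cap matters because `I_down` converges slowly (roughly geometrically) near
homoclinic-type offsets. `confirm_bistability_by_steps()` validates any
detected interval with the five-plateau step protocol (silent at the
intermediate current before activation, firing after), and flags — rather
than hides — any disagreement with the ramp.

`find_equilibria()` reduces the fixed-point problem to a scalar equation in
$V$ (gates at steady state, $Ca^*(V) = f\alpha(-I_{CaL})\tau_{eff}$), scans
−100…+20 mV at 0.5 mV, refines bracketed roots to $10^{-12}$, and classifies
each point by the eigenvalues of a central-difference Jacobian (stable node,
saddle = exactly one unstable direction, unstable). `continuation_diagram()`
tracks the resting and spiking branches quasi-statically in both directions;
their coexistence interval reproduces `[I_down, I_up]` at grid resolution.
No arclength continuation or Floquet analysis is attempted: the
saddle-loop offset is located operationally as the descending-ramp `I_down`.

## Trace quantification

`sadp_metrics()` quantifies the post-stimulus deflection relative to the
holding potential (mean of the 500 ms before the pulse, as in the
experimental convention): signed amplitude (positive = slow
afterdepolarization, negative = afterhyperpolarization), duration at
half-maximal amplitude, and area over a 7.5 s window. Amplitude and duration
are measured on a 50 ms moving mean starting 100 ms after stimulus end — the
smoothing suppresses channel ripple and the margin excludes the passive
repolarization transient (membrane time constant 10 ms), which would
otherwise masquerade as a deflection; the area integral starts at stimulus
end, per the experimental definition. `rate_profile()` computes instantaneous
frequencies from inter-spike intervals, fits a linear trend, and classifies
the train as ramping/adapting/flat with a dead-band of ±5% of the mean rate
per second. `assess_bistability()` applies the three experimental criteria to
holding-ladder traces (`make_holding_ladder()`): downstate before the pulse,
self-sustained firing after it, and reset by a brief hyperpolarizing probe
(−2 µA/cm², 500 ms, 7.5 s after the pulse — the probe's size is not specified
experimentally and is configurable).

## Figure presets and assumed parameters

Presets for every model panel ship as YAML files
(`list_presets()`, `run_preset()`). Each file separates printed parameter
values from an `assumed:` block for values the source figures do not print.
The assumed values were fixed once, against the printed thresholds, and are
not revisited:

* **Bistable reference cell** (`fig2_*`): the printed value is
  $g_{CAN} = 0.5$ with thresholds $I_{up} = 1.7$, $I_{down} = 1.1$ µA/cm².
  With all other modulatory conductances at zero and $[K^+]_o = 4$ mM the
  implementation fires from $\approx 1.25$ µA/cm² and sustains the plateau
  down to zero current, so the unprinted background cannot be all-zero. The
  background $g_{KCa} = 0.5$, $g_{Kv1.2} = 0.1$, $[K^+]_o = 8.2$ mM
  reproduces the printed pair to within 0.03 µA/cm²
  (converged: $I_{up} = 1.698$, $I_{down} = 1.124$).
* **Potassium / NaP switch demonstrations** (`fig5*`, `fig6*`): run at
  $g_{CAN} = 0.55$ instead of the printed 0.9, because in this implementation
  the calcium–CAN feedback is stronger than in the source (see *Known
  discrepancies*) and 0.9 is already bistable at 4 mM. At 0.55 the genuine
  switches appear: no hysteresis at $[K^+]_o = 4$ mM vs. a wide interval at
  8 mM, and none at $g_{NaP} = 0$ vs. a clear interval at 0.45 mS/cm².
* **Sodium-based bistability** (`fig8*`): $g_{NaP} = 0.4$ (unprinted)
  reproduces the printed rest-loss current ($\approx 0.85$ µA/cm²) and
  offset ($\approx 0.45$) at 12 mM potassium; at $g_{NaP} = 0.25$ (printed)
  bistability emerges at 12 mM exactly.
* **Firing-dynamics panels** (`fig9*`): pulse amplitudes are unprinted;
  8 µA/cm² (SK adaptation) and 10.75 µA/cm² (Kv1.2 delayed excitation) are
  used, each with a 100 ms rounded onset so the response reflects the slow
  conductances rather than the step edge.

## What the protocols do and do not show

All inputs are synthetic current programs — the model's "data" are its own
trajectories, generated at run time under the stated conditions. Passing
tests therefore demonstrate internal consistency of the model and protocols
(threshold ordering, ramp/step agreement, classification dichotomies), not
fidelity to any particular recorded neuron: real motoneurons have dendrites,
channel noise, slow ion accumulation and temperature sensitivity, none of
which are modelled. Wet-lab comparisons (pharmacology, population statistics)
are out of scope; drug effects are emulated only as conductance changes.

## Known discrepancies with the source figures

Two quantitative claims of the source could not be reproduced from the
printed equations, and the corresponding acceptance checks are left failing
rather than tuned away:

* **Calcium–CAN loop strength.** The purely sodium-based predictions match
  the source closely (minimal $[K^+]_o = 12$ mM at $g_{NaP} = 0.25$; no
  bistability at 10 mM for $g_{NaP} < 0.5$; rest-loss near 0.85 µA/cm²), but
  every boundary involving the CaL–CICR–CAN loop sits at roughly half the
  published conductance: the $g_{CAN}$ bistability threshold at
  $g_{KCa} = 0.5$ comes out near 0.7 rather than ~1, and the
  $g_{CAN} = 0.9$ control points of the potassium/NaP maps are already
  bistable at 4 mM. Halving the calcium influx term (α → 2.5×10⁻⁴)
  reproduces the published threshold exactly, which localizes the difference
  to the calcium pathway; since α is a printed constant derived from shell
  geometry, the package keeps the printed value.
* **Kv1.2 ramping discharge.** The printed Kv1.2 kinetics produce robust
  *delayed excitation* — at $g_{Kv1.2} = 2$ the membrane stalls below
  threshold for 3–15 s (depending on amplitude) while the channel slowly
  inactivates, then fires — but the discharge after onset holds an
  essentially constant rate at every amplitude examined; a progressively
  accelerating rate was not found. The `fig9b` preset documents the delayed
  onset as its expected outcome.

## Problem sizes

Defaults were chosen for desk-scale runtimes: ramp convergence doubling from
5 s phases capped at 80 s; equilibrium scans at 0.5 mV; continuation and
property tests on coarse current/parameter grids (steps of 0.1–0.2 µA/cm²,
0.1 mS/cm², 0.5 mM); the two-parameter sweep API defaults to whatever grids
the caller supplies, and the shipped analyses use boundary-point scans with
early exit instead of full-density colour maps.
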