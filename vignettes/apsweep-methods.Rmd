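---
title: "Methods: from ion-channel screens to action-potential predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ion-channel screens to action-potential predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apsweep)
```

## Overview

`apsweep` turns a compound's multi-channel potency panel into predicted
changes of the cellular cardiac action potential. The pipeline is:

1. **Dose–response**: convert each channel's pIC50/IC50 (+ optional Hill
   coefficient) into a fraction of current remaining at a given
   concentration;
2. **Conductance block**: multiply the matching maximal conductances of an
   ODE cell model by those fractions;
3. **Pacing**: stimulate the blocked model periodically until a
   pseudo-steady state emerges;
4. **Biomarkers**: measure APD90 and friends on the final pace, flag
   abnormal rhythms;
5. **Study**: repeat over a concentration grid and summarise ΔAPD90%
   relative to the drug-free control.

This vignette records the modelling assumptions, the tunable parameters and
their defaults, the numerical choices, and what the shipped demonstration
model does and does not establish.

## Dose–response model

The fraction of current remaining is $1 / (1 + (C/\mathrm{IC}_{50})^{h})$.
Assumptions inherited from this functional form and from the way screens
are run:

* **Pure conductance block.** The compound scales a current's maximal
  conductance and leaves its kinetics untouched; there is no state- or
  voltage-dependent binding, so no use-dependence can emerge from the block
  itself (only from the cell model's rate-dependent physiology).
* **Instantaneous equilibrium.** The steady-state level of block is applied
  from the first pace; binding kinetics and tissue accumulation are not
  modelled. The simulation must still be paced to steady state because the
  *cell* adapts slowly even when the block is instantaneous.
* **Antagonism only.** Factors are capped at 1; agonist (conductance
  increasing) action is out of scope.
* **Hill default 1.** High-throughput Hill estimates are noisy; a fixed
  Hill of 1 (one molecule blocks one channel) is often the smaller error.
  User-supplied coefficients are accepted in (0, 10].
* **pIC50 convention.** pIC50 $= -\log_{10}$(molar IC50), so
  IC50[µM] $= 10^{6-\mathrm{pIC50}}$. Non-positive IC50 inputs are
  constructor errors — "not measured" must be expressed by *omitting* the
  channel (which then gets a factor of exactly 1), never by coding a zero.
* **Already-fitted inputs.** The package consumes fitted (possibly
  extrapolated) IC50s; it does not fit curves to raw inhibition data.

The six supported channels are the standard screening panel:
IKr (hERG/Kv11.1), ICaL (Cav1.2), INa (Nav1.5), IKs (Kv7.1), IK1 (Kir2.1)
and Ito (Kv4.3, i.e. the fast transient outward current). If a model
carries only a single *total* I<sub>to</sub> conductance, an Ito screen is
applied to that total conductance — the registry flags such models with
`ito_is_total` (the shipped `sixcurrent_demo_totalito` entry exercises this
path).

## The six-current demonstration model

The literature ventricular models live in external repositories; this
package instead ships a compact, fully self-contained stand-in that
exercises every pipeline feature: six independently blockable currents,
realistic AP morphology, and mild stiffness. It is **a demonstration
organism, not a validated human model**: quantitative APD changes on it
support the *machinery*, not clinical translation.

Structure (9 states: $V$ plus 8 gates, all gates with
$\dot g = (g_\infty(V) - g)/\tau_g$ and Boltzmann
$g_\infty = 1/(1+e^{-(V-V_{1/2})/k})$):

* $I_{Na} = g_{Na} m^3 h (V - E_{Na})$ — fast activation
  ($\tau_m = 0.15$ ms) gives the upstroke; inactivation recovers slowly at
  rest (voltage-dependent $\tau_h$, ~12 ms at −85 mV).
* $I_{CaL} = g_{CaL} d f (V - E_{Ca})$ — slow inactivation
  ($\tau_f = 200$ ms) sustains the plateau.
* $I_{Kr} = g_{Kr} x_r (V - E_K)$ — the main repolariser
  ($\tau_{x_r} = 180$ ms).
* $I_{Ks} = g_{Ks} x_s^2 (V - E_K)$ — a deliberately weak backup
  repolariser (see below).
* $I_{K1} = g_{K1} k_{1\infty}(V) (V - E_K)$ — instantaneously rectifying;
  holds the resting potential near $E_K$ and shuts at the plateau.
* $I_{to} = g_{to} r s (V - E_K)$ — the phase-1 notch.

Fixed Nernst potentials ($E_{Na} = 65$, $E_{Ca} = 60$, $E_K = -88$ mV,
the L-type value being an *effective* reversal), no intracellular ion
dynamics. That keeps the state space small and steady state quick to reach,
at the cost of realism: no calcium-transient feedback, no
concentration-driven long-term drift, no use-dependent sodium block.

All kinetic constants are ordinary model parameters (overridable per study
for sensitivity checks), frozen at tuned values and pinned by regression
tests. The tuning targets were: resting potential in [−90, −75] mV, peak in
[+10, +50] mV, APD90 in [200, 350] ms at 1 Hz, steady state within 1000
paces, and the canonical pharmacology directions (IKr block prolongs APD90,
ICaL block shortens it, INa block slows the upstroke). The tuned model
gives rest −88.0 mV, peak +40.0 mV, APD90 252 ms, and converges in 7 paces
at 1 Hz.

Two deliberate tuning choices shape the high-block regime: $g_{Ks}$ is kept
small so that repolarisation reserve genuinely depends on I<sub>Kr</sub>
(heavy hERG block drives APD90 above 700 ms at 1 Hz), and the complete
inactivation of $f$ guarantees the plateau always ends, so at 1 Hz even
total I<sub>Kr</sub> block converges to a long but finite AP. Repolarisation
*failure* appears physiologically — when the prolonged APD no longer fits
the pacing period (e.g. heavy block at 2 Hz), producing 2:1-like rhythms.

The resting equilibrium used as the default initial state was computed by
one-dimensional root-finding on the summed steady-state currents (gates
eliminated at $g_\infty(V)$); the test suite re-derives it independently
and checks the right-hand side vanishes there.

The default stimulus is a square pulse of 2 ms starting 10 ms into the
pace; the demonstration model's amplitude (40 µA/µF) is 1.5× its measured
excitation threshold (~27 µA/µF).

## Numerical engine

* **Solver.** No stiff BDF library is available in the target environment,
  so the engine uses a hand-implemented Dormand–Prince 5(4) embedded pair
  with PI step-size control and the standard 4th-order dense-output
  interpolant. The demonstration model's fastest time constant (0.15 ms) is
  mild enough that an explicit adaptive method is efficient; correctness is
  anchored not to the solver brand but to an *oracle-equivalence* test: the
  adaptive steady-state pace must match a fixed-step classical RK4
  reference at dt = 0.001 ms within 0.5 mV pointwise and 1 ms in APD90.
  The RK4 reference integrator ships in the package (`method = "rk4"`).
* **Tolerances.** Defaults abs 10⁻⁶, rel 10⁻⁸ (the unusual rel < abs
  pairing is kept deliberately as the conventional setting for this
  application); both configurable. A 100× tightening moves APD90 by
  < 0.5 ms (tested).
* **Output.** Dense output is evaluated on the uniform 0.1 ms grid (both
  pace endpoints included); solver-internal steps are never exposed. The
  stimulus pulse bounds the integration segments exactly, so the
  discontinuity never crosses a step.
* **Steady state.** After each pace (from the second onwards) the engine
  computes the Euclidean norm of the raw state change between consecutive
  pace ends — unweighted and in mixed units, deliberately, matching the
  conventional criterion — and stops below 10⁻⁶. The comparison point is
  the pace end; the final two traces are retained for alternans checks. The
  default pace limit is min(1800 paces, 5 simulated minutes).
* **Determinism.** The integrator is deterministic; identical inputs give
  bit-identical traces, and identical CLI invocations byte-identical CSVs.

## Biomarkers and abnormality rules

APD$_p$ is measured from the instant of maximum upstroke velocity (not
stimulus onset — the standard convention) to the first subsequent downward
crossing of $V_{peak} - (p/100)\cdot$amplitude, with linear interpolation
between the bracketing samples; absent (never zero) when the crossing does
not occur. Biomarker computation always uses the full 0.1 ms grid; traces
are down-sampled (default 1 ms) only for export and plotting.

The abnormality rules are documented, configurable stand-ins — the
phenomena are standard, exact thresholds are not published:

* **ALTERNANS**: |APD90(last) − APD90(previous)| > 1 ms.
* **DEPOLARISATION_FAILURE**: peak voltage below 0 mV.
* **REPOLARISATION_FAILURE**: an AP was elicited but 90% repolarisation is
  never reached within the pace — *on either of the two retained paces*.
  The extension to the previous pace matters: in 2:1-like rhythms the pace
  that fails to repolarise is the second-to-last one, and the final pace
  taken alone can look (mis)leadingly normal. A row flagged this way
  reports APD90 and ΔAPD90% as absent; the message carries the details.

## Study design choices

* **Warm start.** Drugged runs start from the control's converged state — a
  large speed-up; a test verifies it changes converged APD90 by < 1 ms on
  the demonstration model.
* **Grid.** Log10 spacing by default (sweeps span decades); linear
  available. The 0 µM control is always prepended and ΔAPD90% is relative
  to the *same-study* control, never to a literature baseline.
* **Failure isolation.** A solver failure on one concentration becomes a
  `SOLVER_FAILURE` message on that row; remaining concentrations still run.
* **Export.** `summary.csv` (one row per concentration; absent values are
  empty cells), one trace CSV per concentration, `metadata.csv` echoing all
  inputs. Ordering is ascending concentration, control first, so identical
  studies export byte-identical summaries.

## What the tests do and do not establish

The suite covers the analytic dose–response identities (half block exactly
at the IC50 for any Hill), solver-vs-reference equivalence, steady-state
contract and fixed-point restarts, closed-form biomarker traces
(square pulse and linear ramp), the pharmacology direction properties, and
end-to-end CLI determinism. All of this is on the demonstration model: a
green suite establishes that the *pipeline machinery* is correct, not that
predictions for any literature cell model or any real compound are
accurate. Known limitations carried by design: no late sodium current, no
Markov/state-dependent drug binding, no calcium subsystem, no uncertainty
quantification of IC50 inputs, single cell only (no tissue, conduction or
QT measures).
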