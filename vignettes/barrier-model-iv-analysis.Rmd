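---
title: "Barrier-model analysis of patch-clamp I-V relations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barrier-model analysis of patch-clamp I-V relations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivperm)
```

## The permeation model

`ivperm` describes open-channel ion permeation as thermally activated
hopping over `n` Eyring barriers. The barriers are equally spaced in
*electrical* distance: peaks at fractional distance $(2j-1)/2n$ from the
intracellular side, wells at $j/n$, each hop sensing half of the voltage
drop across its segment. Wells are equally deep — the model deliberately has
no strong ion-binding site, consistent with the low effective affinity of
Cl⁻ conduction in CaCCs. Two relative rates carry all the shape
information: $\sigma_\beta$ for the innermost barrier and $\sigma_h$ for the
middle barrier(s), both expressed relative to the outermost barrier whose
rate is fixed at 1. With $u = zFV/RT$ the steady-state current is

$$I(V) = zFA\, e^{u/2n}\,
  \frac{c_{in} - c_{out}e^{-u}}
       {e^{-u(n-1)/n} + \frac{1}{\sigma_h}
        \frac{1-e^{-u(n-2)/n}}{e^{u/n}-1} + \frac{1}{\sigma_\beta}}$$

Voltage convention: $V = V_{in} - V_{out}$, positive current is outward
movement of positive charge, so with $z=-1$ chloride influx at depolarized
potentials is positive — the sign convention of CaCC recordings.

Three analytic facts anchor the implementation, and the test suite checks
all of them:

1. **Equal-barrier limit.** With $\sigma_\beta=\sigma_h=1$ and symmetric
   concentrations the denominator telescopes to a geometric sum and the
   current collapses to $2zFAc\,\sinh(u/2n)$ for every $n \ge 2$.
2. **Nernst reversal.** The numerator vanishes identically at
   $V = (RT/zF)\ln(c_{out}/c_{in})$, so the model reverses exactly at the
   Nernst potential of the permeant ion for *any* barrier profile: the
   model channel is perfectly anion selective by construction.
3. **Chain equivalence.** The closed form is algebraically identical to the
   steady-state solution of the explicit hopping chain with per-barrier
   rate multipliers $\gamma = (\sigma_\beta, \sigma_h, \dots, \sigma_h, 1)$:
   the chain's flux denominator is
   $\sum_m \gamma_m^{-1} e^{-u(m-1)/n}$, which regroups into the printed
   form. `hopping_chain()` + `steady_state_flux()` implement the chain
   independently (solving the linear master equation for the internal well
   occupancies) and serve as the package's internal oracle. The chain also
   expresses what the two-sigma form cannot: raising only the *outermost*
   barrier, which produces inward rectification.

The typeset grouping of such equations is easily mangled; the grouping used
here was adopted because it is the unique reading that (a) yields the pure
sinh equal-barrier limit, (b) reproduces the qualitative
barrier-position-to-rectification map (inner barrier up → outward; outer
barrier up → inward; middle barrier up → suppression in both directions with
$RI$ staying at 1, which the form makes exact when $\sigma_\beta = 1$), and
(c) matches the independent chain solver to machine precision. Any
implementation change must re-pass the chain-equivalence test before being
accepted.

Energy offsets are reported as $\Delta E_a = -RT\ln\sigma$ in kJ/mol:
$\sigma < 1$ (slower than the outermost barrier) maps to a positive offset,
i.e. a higher barrier. Only *offsets relative to the outermost barrier* are
defined; absolute barrier heights are not identifiable from I-V data and are
never reported.

## Parameters that matter

| parameter | unit | default | rationale |
|---|---|---|---|
| `n_barriers` | – | 3 | a three-barrier profile is the smallest that separates inner / middle / outer effects; treated as a fixed structural choice, never fitted continuously. `fit_sensitivity()` refits at n = 3, 4, 5. |
| `sigma_beta`, `sigma_h` | – | 1 | relative rates; 1 = all barriers equal (quasi-linear I-V) |
| `amplitude` | current · mM⁻¹ / (zF) | 1 | multiplies $zF$ as in the current equation; cancels on normalized curves. The generator calibrates it so a healthy patch carries 500 pA at +120 mV. |
| `temperature_K` | K | 295 | room temperature; the recording temperature is an assumption, configurable. RT/F ≈ 25.42 mV. |
| fit bounds | – | $\sigma \in [10^{-3}, 10^{3}]$ | six decades comfortably contain every physically sensible profile while keeping the search bounded |

## What the synthetic data emulate — and what they do not

`simulate_patch()` generates the instantaneous-current step protocol: a
+80 mV pre-pulse followed by one test step per sweep (−100…+120 mV in 20 mV
increments by default, so that +120 mV for normalization and ±100 mV for the
rectification index always exist), sampled at 20 kHz with a 5 kHz filter
recorded as metadata. The emulated artefacts are exactly the ones the
preprocessing chain exists to remove:

* **Rundown.** Channel availability decays as $a_s = e^{-s/\tau}$ over the
  sweep index $s$, *multiplicatively and identically* at the pre-pulse and
  the test step of a sweep. This is the premise that makes pre-pulse-based
  correction exact; it holds for a slow loss of active channels, not for
  voltage-dependent inactivation.
* **Leak.** An ohmic background $g(V - V_{off}) + I_0$, present with and
  without intracellular Ca²⁺, so that the paired Ca²⁺-free background
  recording removes it exactly.
* **Voltage offset.** A per-patch shift of the apparent I-V along the
  voltage axis, drawn uniformly from ±3 mV so the <2 mV acceptance rule
  rejects about a third of patches; measured from a symmetric-solution
  recording and subtracted from reversal potentials.
* **Noise and patch variability.** Gaussian sample noise (default 10 pA =
  2% of the calibrated +120 mV response) and lognormal patch-to-patch
  amplitude scatter (CV 0.3, a typical spread for macroscopic patches).
* **Capacitive transients** are represented only as a 0.5 ms dead time after
  each step during which samples are unusable; no RC physics is simulated.

Deliberately absent: gating kinetics (currents are instantaneous — the
experimental design saturates activation at 1 mM Ca²⁺ precisely to make
this a good approximation), single-channel stochasticity, series-resistance
error, liquid-junction potentials, and any cation permeability (the model
channel is perfectly Cl⁻ selective; a Na⁺-permeable channel would deviate
from the Nernst line in a way these simulations cannot produce). Passing
tests therefore demonstrate that the *pipeline* is correct and
well-conditioned under realistic noise — not that real TMEM16A data are free
of the excluded effects.

The generator is deterministic: every dataset derives all per-patch seeds
from one master seed.

## Preprocessing rules

Corrections apply in a fixed order, tracked by state flags that only move
forward: background subtraction → rundown correction → normalization.

* Instantaneous currents are the mean of the samples 0.5–2.0 ms after each
  voltage jump (after the dead time, well inside both segments; ~30 samples
  at 20 kHz). The window is configurable but validated against the
  protocol.
* The rundown reference is the **first** sweep's pre-pulse — the sweep with
  maximal availability. A reference below 1% of the largest pre-pulse
  current aborts the correction rather than amplifying noise.
* Normalization divides by the current at +120 mV, per patch, after rundown
  correction; replicate patches are averaged pointwise with s.e.m.
* The voltage offset is the zero crossing of the symmetric-condition I-V,
  linearly interpolated between the bracketing voltages — the same estimator
  used for reversal potentials, so offsets and reversals are read
  consistently. Patches at or above 2 mV are excluded. Offsets are
  subtracted per patch where symmetric data exist; otherwise the averaged
  offset is subtracted from the averaged reversal potential
  (`selectivity_table()` accepts either a QC report or a plain averaged
  offset).

## Fitting

Normalized curves make the amplitude drop out: the model is evaluated
normalized to its own +120 mV response, leaving $(\sigma_\beta, \sigma_h)$.
Both are searched in log space — they span decades and the model is smooth
in $\ln\sigma$ — within $[10^{-3}, 10^{3}]$, by bounded quasi-Newton
iteration from a 3×3 grid of log-spaced starts; the best converged start
wins, making the fit deterministic. Weights are $1/\mathrm{sem}^2$ when
standard errors are available (points with zero s.e.m., such as the
normalization point, get zero weight — their residual is identically zero
anyway). Confidence intervals come from the local curvature (Hessian) at
the optimum and are **descriptive only**: barrier models are phenomenology,
and the package never interprets the fitted profile as a literal map of the
pore.

Numerical details worth recording:

* The removable singularity of the denominator quotient at $V=0$ is
  evaluated through `expm1()`, which stays accurate arbitrarily close to
  zero; the analytic limit $n-2$ is substituted only below $|u/n| <
  10^{-12}$. The even part of the current at $\pm 10^{-6}$ mV matches the
  limit value to better than $10^{-8}$ relative error.
* A multistart that lands exactly on the optimum can terminate with an
  "abnormal line search" code while returning the exact minimizer;
  convergence is therefore judged against the best cleanly-converged start,
  value-aware.
* Zero crossings: an exact zero wins; exactly one sign change is
  interpolated; no sign change or several (noisy flat curves) raise typed
  errors (`ivperm_out_of_range`, `ivperm_ambiguous_reversal`) instead of
  guessing.
* Nernst calculations use concentrations, not activities, matching how
  selectivity data are plotted against concentration.
* Solution bookkeeping treats free Ca²⁺ as total Ca minus EGTA — the
  working-concentration convention (5.99 mM Ca(OH)₂ against 5 mM EGTA ≈
  1 mM Ca²⁺) — not a multi-equilibrium speciation model. Irrelevant to
  permeation analysis, documented as a limitation.

## Problem sizes

The simulation-based checks run at the scale of the underlying study
design: 12 patches per construct (8–15 is the experimental range, and the
~2/3 QC acceptance of a ±3 mV offset population lands the accepted count in
exactly that range), 2% sample noise, rundown τ = 5 sweeps for
identity checks and τ = 20 for realistic datasets, 20 seeded replicates per
ground truth in the recovery study ($\ln\sigma_\beta \in \{\ln 1, \ln 0.3,
\ln 0.1\}$, recovery within ±0.2 log units), four intracellular dilutions
(150/75/37.5/15 mM) for the Nernst-line slope, and 1000 patches for the QC
acceptance fraction. `scripts/acceptance.R` recomputes all of these from
scratch for any seed.

## Known limitations

* The model is linear in concentration — no saturation, no multi-ion
  single-file effects; `concentration_conductance()` can fit a saturating
  hyperbola but on model-generated data its half-maximal concentration is
  unbounded, and the function says so rather than reporting a spurious
  affinity.
* Only barrier-height *offsets* are identifiable; absolute energies and the
  electrical positions of the barriers are fixed assumptions.
* The offset and reversal estimators interpolate linearly between 20 mV
  grid points; with 2% noise the single-patch reversal carries a few tenths
  of a millivolt of jitter, which is why selectivity conclusions are drawn
  from patch-averaged curves.
* GHK-style permeability ratios are intentionally out of scope; selectivity
  is assessed against the Nernst line only.
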