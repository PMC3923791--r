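---
title: "Triplet STDP and its subthreshold synapse circuit: models, protocols, fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triplet STDP and its subthreshold synapse circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tstdp)
```

## The plasticity rules

Spike-timing-dependent plasticity (STDP) changes a synaptic weight according
to the relative timing of pre- and post-synaptic spikes. The pair-based rule
(PSTDP) potentiates by $A^+ e^{-\Delta t/\tau_+}$ when a pre-synaptic spike
precedes a post-synaptic one by $\Delta t > 0$, and depresses by
$A^- e^{-\Delta t'/\tau_-}$ for the reverse order. Throughout this package
the sign convention is $\Delta t = t_{post} - t_{pre}$, so positive lags are
causal.

The triplet rule (TSTDP) adds second-order terms that read the time since
the *previous same-train* spike. On every post-synaptic spike at time $t$:

$$\Delta w^+ = e^{-\Delta t_1/\tau_+}\,
  \bigl(A_2^+ + A_3^+\, e^{-(\Delta t_2 - \epsilon)/\tau_y}\bigr),$$

with $\Delta t_1$ the lag to the nearest pre-synaptic spike, $\Delta t_2$
the lag to the previous post-synaptic spike (the $A_3^+$ term is present
only when one exists), and $\epsilon$ a small positive offset ensuring the
triplet trace is read just before the current spike (default $10^{-6}$ s).
Every pre-synaptic spike mirrors this with $A_2^-, A_3^-, \tau_-, \tau_x$.
Interactions are *nearest-spike*: each spike supersedes all earlier spikes
of its own train. We implement this as trace variables that reset to 1 on
each same-train spike, which is equivalent to remembering only the last
spike time of each train; a brute-force oracle that explicitly searches each
opposite train for the nearest predecessor is kept in the test suite as an
independent cross-check, and the factorized evaluation above is verified
against the expanded two-term arrangement (an algebraic identity) on
randomized trains.

Two minimal variants matter in practice: the *hippocampal* minimal rule sets
$A_3^- = 0$; the *visual-cortex* minimal rule additionally sets $A_2^+ = 0$.
`hippocampal_params()` and `visual_cortex_params()` provide representative
nearest-spike values ($\tau_+ = 16.8$ ms, $\tau_- = 33.7$ ms,
$\tau_x = 101$ ms, $\tau_y$ 40-48 ms, amplitudes of order
$10^{-3}$-$5\times 10^{-2}$). They are defaults in the style of published
fits, not fitted constants: the two classical experimental weight-change
tables (13 hippocampal points, 10 visual-cortex points) are external data
that users can transcribe into the CSV dataset format; nothing in this
package requires them.

## Stimulation protocols

`make_pairing()`, `make_triplet()`, `make_extra_triplet()`,
`make_quadruplet()` and `make_poisson_pair()` generate the standard
protocols: 60 repetitions (configurable) of a pair / triplet / quadruplet at
a repetition frequency $\rho$, or independent Poisson pre/post trains for
rate-based experiments. Choices worth stating:

* **Quadruplet anchor.** The separation $T$ is measured between the two
  *inner* spikes (for $T>0$: post–pre ... pre–post with the two pre spikes
  $T$ apart). The protocol literature fixes the ordering but not the
  measurement points; this anchor makes the total span exactly
  $2\,\Delta t + |T|$.
* **Extra-triplet timings.** For the six three-spike orders, `dt1`/`dt2` are
  the timings of the leftmost/rightmost adjacent spike pairs. Positive
  values are read as gap magnitudes (the order is carried by the combo
  label); a negative value is interpreted under the global
  $t_{post}-t_{pre}$ convention and must then agree with the label, else the
  call errors. The exact grid spacing used in the original figures is not
  recoverable from text, so `extra_triplet_grid()` takes the grid as an
  argument.
* **Poisson refractory gap.** Poisson trains are thinned so consecutive
  onsets are at least one pulse width apart — overlapping pulses are
  physically meaningless for the circuit. At the default 1 ms pulse width
  this removes about $\rho \cdot 1\,\mathrm{ms}$ of spikes (1% at 10 Hz).
* All trains live on the biological timescale; the 1000x acceleration is
  applied only inside the circuit simulators.

## The behavioral circuit model

The synapse circuit realizes the triplet rule with 18 transistors (full
rule), 14 (hippocampal minimal, no triplet-depression branch) or 13 (visual
cortex minimal, additionally no pair-potentiation branch). We model it
behaviorally, not at netlist level: every transistor acts only through the
saturation-region subthreshold exponential $I = I_0 e^{\kappa V_g/U_T}$.
Bias voltages map to *effective parameters* (`biases_to_effective()`):

* amplitude branches: $I_X = I_0 e^{\kappa V_X / U_T}$;
* ramp branches: a control transistor sources
  $I_{ramp} = I_0 e^{\kappa(V_{dd}-V_t)/U_T}$ onto a node capacitor
  $C$ (5 fF default), so after a triggering pulse grounds the node it rises
  linearly and the branch current decays with
  $\tau = C\,U_T/(\kappa I_{ramp})$. Once the node reaches the supply —
  after $window = \tau\,\kappa V_{dd}/U_T$, about $89\tau$ at the defaults —
  the branch contributes nothing (the current is below
  $I_0 e^{-\kappa V_{dd}/U_T}$ and is treated as zero).

The weight lives on a 1 pF capacitor $C_w$ and is clamped to the supply
rails $[0, V_{dd}]$. Each triggered branch deposits
$\Delta V_w = (\Delta t_{spk}/C_w)\, I_{branch}$ per spike
(`simulate_event()`), with $\Delta t_{spk} = 1\,\mu s$ pulses on the 1000x
accelerated timescale; results are reported back in biological time. The
triplet branches are driven by internally delayed copies of the trains (one
pulse width late, via `delay_train()`), which is why the circuit's triplet
term carries a one-pulse-width offset where the mathematical rule carries
$\epsilon$.

One bias field goes beyond the six printed ones: the triplet-depression
branch needs its own amplitude control (`V_A3m`, default 0 V, i.e. the
branch is off at the $I_0$ floor), since tying its amplitude to the ramp
bias would conflate $A_3^-$ with $\tau_x$. The six printed optimised bias
voltages are shipped as `table1_biases()` with an explicitly uncertain
column order (the published headers are placeholders); default biases are
instead *derived* from rule-level parameters by inverting the mapping
(`biases_for_effective()`), which also fixes the volt-to-fraction conversion
$C_w/(\Delta t_{spk}\cdot s_I)$, with $s_I$ the amperes-per-unit-amplitude
scale (default $2\times 10^{-7}$ A, placing typical amplitudes in the
nanoampere subthreshold range).

### Two simulators, one model

`simulate_event()` evaluates the analytical expressions per spike.
`simulate_ramp_ode()` instead steps the internal nodes explicitly: nodes are
grounded by their triggering pulse, rise linearly at their bias-set slope,
clamp at the supply, and branch currents are integrated over each gating
pulse with a midpoint rule at resolution `step` (at most one tenth of the
pulse width); between pulses the nodes are advanced analytically because
they are exactly piecewise linear. Numerical choice: node ramps are
referenced to their triggering pulse's *midpoint*. Referencing them to the
pulse end (or start) leaves a systematic $e^{\pm pw/\tau}$ bias of a few
percent per branch which the potentiation/depression difference amplifies;
midpoint alignment cancels it to second order, and the two simulators then
agree to well under 1% across the pairing, triplet and quadruplet
protocols (the cross-validation in the tests allows 5%). With windows set to
infinity and matched amplitudes/time constants the event simulator is
*exactly* the triplet rule scaled by $\Delta t_{spk}/C_w$ — that identity is
a test, with the rule's $\epsilon$ set to the accelerated pulse width.

Ties (a pre and post pulse at the same instant) are processed pre-first, so
a coincident pair contributes a potentiation at zero lag; the deterministic
protocols never produce coincidence. The rule-level weight is unbounded;
saturation exists only in the circuit, where the rails impose it.

## Fitting

Goodness of fit is the normalized mean square error
$\mathrm{NMSE} = \frac{1}{N}\sum_i \bigl((\Delta w^{exp}_i -
\Delta w^{sim}_i)/\sigma_i\bigr)^2$ with $\sigma_i$ the per-point standard
error of the mean. Optimisation is a derivative-free Nelder-Mead simplex
(`optimize_simplex()`, delegating the simplex core to `stats::optim`), with
box bounds handled by projecting candidates into the feasible region,
automatic restarts from the projected incumbent (a fresh simplex recovers
from collapse against the projection boundary; 1-D searches use a coarse
scan plus golden-section refinement instead), and seeded multi-start.
Default bounds are typical STDP ranges — amplitudes in $[0, 0.1]$, time
constants in $[1, 200]$ ms — and supply rails for bias voltages.

Because the rule is linear in its four amplitudes at fixed time constants,
amplitude-only fits precompute a design matrix from four unit-amplitude
runs and evaluate the objective algebraically; the simplex is unchanged.
For the circuit engine the single global scale factor between capacitor
volts and fractional weight change is profiled analytically by weighted
least squares at every objective evaluation — the same co-optimisation the
fitting procedure would do numerically, done exactly. Weight changes are
fractions internally; percent only at I/O.

`make_synthetic_dataset()` provides ground-truth datasets for testing and
parameter recovery: it computes true weight changes on a protocol grid
(default: the 2 pairing + 3 quadruplet + 8 triplet hippocampal composition,
with $\Delta t = \pm 10$ ms, $T \in \{-100, -30, 30\}$ ms and
$(\Delta t_1, \Delta t_2) \in \{(5,5), (10,10), (5,15), (15,5)\}$ ms for
both triplet orders), assigns $\sigma_i = \max(0.1\,|\Delta w_i|, 0.01)$,
and perturbs the means with Gaussian noise of SD `noise_scale`$\cdot\sigma_i$.
At `noise_scale = 1` the NMSE of the generating parameters is a reduced
chi-square with expectation 1, which calibrates what a "good" fitted NMSE
means on such data. The generator emulates the *composition and error
structure* of the experimental tables, not their actual values: passing
recovery tests shows the estimator works on data of that shape and noise
level, not that the defaults reproduce any laboratory measurement.

## Rate-based (BCM-like) behaviour

`bcm_sweep()` fixes the pre-synaptic Poisson rate (10 Hz) and sweeps the
post-synaptic rate over 0-50 Hz with 10 independent trials per point,
reporting mean and SD of the total weight change; `bcm_sweep_pre_driven()`
sets $\rho_{post} = \rho_{pre}$ (the linear-neuron simplification). With
visual-cortex-style parameters the mean curve is zero at $\rho_{post}=0$,
depressing at low rates and potentiating at high rates, with a single
crossing near 10 Hz that slides with $A_2^-$ (roughly 5/10/20 Hz at
$A_2^- \times \{0.5, 1, 2\}$) — the BCM-like modification threshold.
Trial duration is not specified by the protocol descriptions; the default
is 20 s per trial, chosen once so that the mean drift dominates the
trial-to-trial SD everywhere except immediately at the crossing.

## Transistor mismatch

`run_mc()` draws i.i.d. threshold-voltage deviations
$\mathcal{N}(0, \sigma_{V_{th}})$ for every transistor active in the
variant ($\sigma_{V_{th}} = 10$ mV by default, so the three-sigma point is
30 mV), maps them onto the effective parameters with `apply_mismatch()`,
and re-scores the fixed-bias circuit on every dataset protocol. The
label-to-parameter mapping is fixed: amplitude transistors (M7, M12, M16,
M3) scale their branch current by $e^{-\kappa\,\delta V_{th}/U_T}$; the
series transistors M8/M11/M15 scale every current they carry; ramp-control
transistors (M5, M14, M17, M2) scale their ramp current, hence $\tau$ and
window by $e^{+\kappa\,\delta V_{th}/U_T}$; pure pulse switches (M1, M4,
M6, M9, M10, M13, M18) are inert in the behavioral abstraction. The
volt-to-fraction scale is profiled once at the unperturbed baseline and
held fixed across runs, mirroring fixed biases.

Known limitation: this abstraction routes each deviation *directly* into an
amplitude or time constant ($\pm 31\%$ per 10 mV at $\kappa/U_T = 27\,
\mathrm{V^{-1}}$), with no compensating series interactions, so the NMSE
distribution is substantially broader than a netlist-level simulation of
the same scenario would give — right-skewed, with the median an order of
magnitude above baseline at $\sigma_{V_{th}} = 10$ mV. The properties that
are scenario-independent hold and are tested: the distribution is
degenerate at $\sigma_{V_{th}} = 0$, its spread grows monotonically with
$\sigma_{V_{th}}$, and everything is bit-reproducible under the config
seed.

## Problem sizes and determinism

The test suite and the acceptance script keep simulations at sizes chosen
for tight statistical margins at interactive runtimes: identity checks on
hundreds to a thousand randomized train pairs, cross-validation on 14
protocol configurations, BCM sweeps of 15 rates x 10 trials x 20 s,
recovery over 10 seeded datasets, and 1000-run Monte Carlo. Every stochastic
component takes an explicit seed and derives independent substreams from
it, so all reported numbers are exactly reproducible.

## Other limitations

Weight-capacitor leakage between protocol repetitions, bistable weight
storage, spike-delivery (AER) transport and energy/area estimation are out
of scope; all-to-all spike interaction and weight-dependent update rules
are not implemented (nearest-spike only); Poisson trains are homogeneous.
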