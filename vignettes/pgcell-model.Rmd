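---
title: "The pgcell periglomerular cell model: mechanisms, numerics and scope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pgcell periglomerular cell model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pgcell)
```

## The model

Periglomerular (PG) cells are GABAergic interneurons of the olfactory bulb
glomerular layer. Slice recordings show a wide range of responses to
somatic current steps — non-accommodating and accommodating spike trains,
single spikes, irregular firing, low-threshold calcium spikes (LTS)
crowned by one or several decrementing sodium spikes, and rare persistent
plateau potentials. `pgcell` implements the hypothesis that this
heterogeneity needs no qualitative differences between cells: a single
reduced cell with fixed channel kinetics reproduces the phenotype range
when only the maximal conductance densities change.

The cell has six sections: a soma of 8 µm length and diameter, two 20 µm
dendrites of 1 µm diameter, a 1 µm gemmule shaft and gemmule attached to
dendrite 1, and a 50 µm axon stub. Passive constants are
C~m~ = 1.2 µF/cm², R~axial~ = 173 Ω·cm and a leak reversal of −70 mV (one
preset requires −55 mV, see below). Spatial discretization follows the
d_lambda rule — each compartment no longer than a tenth of the AC length
constant at 100 Hz — giving three axon compartments and one isopotential
compartment per remaining section (`compartmentalize()`); tripling all
compartment counts changes somatic voltages by under 0.03 mV
(asserted in the acceptance suite at 0.1 mV).

Each compartment integrates the usual cable-coupled current balance; every
gated current takes the Hodgkin–Huxley form
$I_x = G_{max}\, m^a h^b (V - E_x)$ with gating relaxation
$dm/dt = \Phi\,(m_\infty - m)/\tau_m$. The mechanism set is: fast sodium
(m³h, Φ = 0.24, E = +50 mV), delayed-rectifier potassium (m⁴, Φ = 0.24),
A-type potassium (mh, Φ = 0.46), calcium-dependent potassium (m²,
Φ = 1.12; all potassium reversals −85 mV), hyperpolarization-activated
cation current H (m, Φ = 0.35, E = 0 mV), L-type calcium (m² with an
instantaneous calcium-dependent inactivation gate
$h = 1.245/(1.245 + [Ca]_i)$, Φ = 1), low-threshold T-type calcium (m²h,
Φ~m~ = 0.85, Φ~h~ = 0.90), calcium-activated nonspecific cation current
CAN (m², Φ = 1.12, E = 0 mV), plus two ohmic conductances: the leak and a
nicotinic cation conductance (E = +3.2 mV) in the gemmule. Kinetics are
pinned at 23 °C through the fixed Φ values; there is no further Q10
machinery. The full rate equations live in the compiled kinetics core and
can be dumped as delimited-text tables with `dump_gating_curves()`;
`channel_catalog()` exposes the orders, Φ values and reversal rules as
data. The temperature coefficient enters only the state-update equation,
so steady states are Φ-independent; the τ floors of the calcium-gated
gates (`max(·, 0.1)` ms) are applied to τ before Φ scales the derivative.

Calcium entering through the L- and T-type channels feeds a perimembrane
shell 0.1 µm deep whose concentration decays exponentially to a basal
0.24 µM; influx only — an outward calcium flux never depletes the shell
below basal. The calcium reversal potential is a per-compartment Nernst
potential against 2 mM external calcium at 296.15 K, recomputed every
step, so E~Ca~ falls as the shell loads.

## Parameters that matter

* `gmax` (S/cm², per channel): the phenotype dial. The nine presets
  `fig2A` … `fig3E` carry the published densities verbatim (absent entries
  are explicit zeros) and load with their published current-clamp
  protocols via `load_preset()`.
* `g_leak` (S/cm²): not free. `calibrate_leak()` root-finds the uniform
  density at which the passive cell's somatic input resistance equals
  775 MΩ (the measured value); the result, 2.649 × 10⁻⁴ S/cm², is stored
  in the default config and verified by simulation in the test suite.
* `e_leak` (mV): −70 everywhere except the non-accommodating preset
  (`fig2A`), which requires −55 mV.
* Calcium shell: `basal_mM` 2.4e-4, `shell_depth_um` 0.1, and
  `tau_decay_ms` 5. The decay constant is the one genuinely open constant
  of the shell mechanism. We use the 5 ms of the submembrane-shell
  mechanism lineage this model descends from; with slow decay (≥ 20 ms)
  the resting T-type window current alone loads the shell to tens of µM,
  which collapses E~Ca~ (and, for the plateau presets, opens CAN at rest),
  abolishing the LTS phenotypes — so the fast constant is also the only
  self-consistent choice here.
* Ca(T) placement (`cat_scope`): the conductance table annotates the
  T-type column "(soma)", but the published conductance time courses are
  recorded in the primary dendrite, and with strictly somatic Ca(T) no
  current step of any size evokes an LTS in this implementation. The
  default is therefore uniform expression (`"all"`), with `"soma"`
  available as a switch. All other active channels are expressed
  uniformly in every section — the per-section expression matrix of the
  original figure is not recoverable from the text, so uniformity is the
  declared assumption — and the nicotinic conductance only in the gemmule
  (`nic_scope = "all"` spreads the same total conductance uniformly).
* Noise: 50 fA (0.05 pA) Gaussian white source sampled at 0.125 ms (8 kHz,
  so band-limited to 0–4 kHz by the sampling rate alone), colored by
  discrete convolution with an exp(−t/5 ms) kernel, implemented as the
  equivalent first-order recursive filter. The stated SD is the SD of the
  white source *before* coloring; the colored series' SD is whatever the
  (unnormalized) convolution yields, ≈ 0.22 pA at this sampling rate.

## Numerics

The integrator is a fixed-step, second-order implicit scheme:
Crank–Nicolson for the voltages with a Hines-ordered elimination over the
branched topology, staggered with exact exponential-Euler updates of the
gating states and the shell calcium (both have closed-form solutions over
a step for frozen coefficients). The default dt is 10 µs. Each run starts
from a uniform voltage with gates at steady state and settles with no
stimulus until every compartment's |dV/dt| < 10⁻⁶ mV/ms (2 s minimum,
extended in 0.5 s blocks, 10 s cap — the H and CAN gates have ~1 s
effective time constants near rest); the settle phase is discarded.
Noise simulations always use this fixed-step backend, since adaptive
stepping would change the realized noise path.

Convergence, asserted in the acceptance suite: halving dt leaves
subthreshold somatic trajectories within 0.05 mV in max-norm (measured:
4 × 10⁻⁵ mV) and spiking trajectories with identical spike counts and
spike times within 0.2 ms (measured: no shift at the 0.05 ms recording
resolution). Max-norm is the wrong metric across a spike upstroke — at
200 mV/ms a half-microsecond phase shift already exceeds 0.05 mV — which
is why spiking traces are compared by spike timing. The solver was
validated against an independent `deSolve::ode` (lsoda, rtol 10⁻⁹)
integration of a lumped isopotential version of the cell, agreeing to
better than 0.1 mV. Degenerate inputs: a non-finite voltage aborts with a
diagnostic; a passive cell initialized at its leak reversal is an exact
fixed point.

## Analysis layer and classifier

`detect_spikes()` finds upward crossings of −20 mV separated by ≥ 2 ms.
The LTS is detected on a pharmacological companion trace with the fast
sodium conductance set to zero (so spikes cannot mask the envelope): a
depolarizing envelope exceeding 10 mV above the pre-window baseline for at
least 20 ms. A plateau is a post-offset potential staying > 20 mV above
rest for > 100 ms, with duration measured from stimulus offset to
half-repolarization (censored at the end of the trace, and flagged as
such). Classification precedence: plateau → LTS with ≤ 1 spike
(`LTS-single-AP`) → LTS with ≥ 2 strictly decrementing spike peaks
(`LTS-burst`) → irregular (noise enabled, ≥ 3 spikes, ISI CV > 0.5;
noiseless traces never classify as irregular) → non-accommodating vs
accommodating by last-ISI/first-ISI against 1.3 (≥ 3 spikes) →
single-spike. All thresholds are declared operationalizations — the source
phenotypes were defined by visual correspondence to recordings — collected
in `analysis_options()` and pinned by the preset regression. A
two-spike train that triggers no other rule is labelled accommodating
(too short to call a steady train); a rebound burst requires ≥ 2
post-release spikes.

`make_synthetic_trace()` builds piecewise waveforms (triangular spikes at
prescribed times, square steps, relaxing sag, post-offset shelves) with
exactly known features; the detector unit tests run against these, so they
test the analysis layer independently of the simulator. These synthetic
traces deliberately lack channel noise, spike afterpotentials and
frequency adaptation structure, so passing detector tests says nothing
about detector robustness on noisy experimental recordings.

## What reproduces, and what does not

The preset regression (`classify_all()`, also the acceptance suite's
behavioral block) simulates each preset under its published protocol pair
(settle, then 600 ms steps — 200 ms for the plateau depolarization — with
400–3000 ms post-stimulus windows, dt = 10 µs). Under this
implementation's reading of the published model — ohmic currents with
Nernst E~Ca~, passive-cell leak calibration to 775 MΩ, uniform channel
expression:

* Reproduced: the non-accommodating train (`fig2A`), the accommodating
  train (`fig2B`), all three plateau presets (`fig3C–E`, including
  insensitivity of the plateau to T-type block), the depolarization-evoked
  LTS of `fig3A` at its printed 10 pA (crowned here by two decrementing
  spikes rather than one), the `fig2D` sag and rebound burst, and the LTS
  pharmacology (sodium block preserves the envelope and silences spikes;
  T-type block abolishes it).
* Not reproduced at the printed stimulus amplitudes: the `fig2C` single
  spike (a 25 pA step into a 775 MΩ cell resting at −71 mV tops out near
  −51 mV, short of the ~−43 mV firing threshold of these sodium
  kinetics), the rebound LTS of `fig3A`/`fig3B` and the `fig3B` burst
  (the T current is roughly 1.5–3× too weak at subthreshold voltages),
  and irregular firing in `fig2D` (the 50 fA noise source perturbs ISIs
  far below the CV = 0.5 criterion). Scaling experiments and an
  independent-solver cross-check locate these in the model reading, not
  the numerics; an alternative leak calibration against the *active*
  reference cell fixes some LTS behaviors but breaks the simple-spiking
  and plateau presets, and was rejected.
* The CAN plateau here is a stable depolarized state rather than a
  1–2 s transient: presence and its T-type-independence reproduce, but
  duration orderings between presets are not measurable (durations are
  window-censored, and the corresponding acceptance assertion fails
  honestly).

## Problem sizes

The shipped defaults are the study conditions: 8 compartments, dt = 10 µs,
2–10 s settle, 1.1–3.3 s recorded windows, nine presets × two polarities
(plus sodium-blocked companions) for the regression, and 10⁶ noise samples
for the source statistics. The full test suite runs in roughly ten
minutes on one core.

## Limitations

Single reduced morphology (no reconstructed arbors); no synaptic receptor
models beyond the ohmic nicotinic conductance, no transmitter release at
the gemmule, no network coupling; no voltage clamp; ohmic calcium currents
with Nernst reversal rather than a constant-field formulation; one
calcium shell per compartment with a single decay constant; no stochastic
channel gating (the only noise is the injected current source); no
fitting machinery for deriving new conductance sets from recordings.
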