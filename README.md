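# pgcell

A conductance-based compartmental model of olfactory bulb **periglomerular
(PG) cells** for R. PG cells are small inhibitory interneurons of the
glomerular layer whose recorded firing patterns are strikingly
heterogeneous — simple non-accommodating or accommodating spike trains,
single spikes, irregular firing, T-type-calcium low-threshold spikes (LTS)
crowned by one or a burst of sodium spikes, and rare persistent plateau
potentials. This package implements a reduced six-section PG cell in which
that whole phenotype range arises purely from different **expression levels**
(maximal conductance densities) of a fixed set of membrane mechanisms, with
channel kinetics held constant. It is aimed at computational
neuroscientists who want a compact, well-tested PG cell building block for
cellular or network simulations, or a worked example of a multi-compartment
Hodgkin–Huxley simulator in R.

## The model

Six cylindrical sections — soma (8 × 8 µm), two 20 µm dendrites, a 1 µm
gemmule (spine) shaft and gemmule on one dendrite, and a 50 µm axon —
discretized by the d_lambda rule (3 axon compartments, 1 elsewhere;
C_m = 1.2 µF/cm², R_axial = 173 Ω·cm, E_leak = −70 mV). Each compartment
obeys the cable-coupled current balance

```
C_m dV/dt = −I_leak − I_Na − I_K − I_K(A) − I_K(Ca) − I_H − I_Ca(L)
            − I_Ca(T) − I_CAN − I_nic − Σ I_adj + I_inj
```

with every channel current in Hodgkin–Huxley form
`I_x = G_max · m^a · h^b · (V − E_x)`, gating states relaxing as
`dm/dt = Φ (m∞ − m)/τ_m` with per-channel temperature coefficients Φ
(kinetics pinned at 23 °C). The K(Ca) and CAN gates and the Ca(L)
inactivation read a perimembrane calcium shell (0.1 µm deep, exponential
decay to 0.24 µM) fed by the calcium currents, whose reversal E_Ca is a
per-compartment Nernst potential. The uniform leak density is not a free
parameter: it is calibrated once so the passive cell's somatic input
resistance equals the measured 775 MΩ. An optional colored current noise
source (50 fA white, 0–4 kHz, convolved with a 5 ms exponential kernel) and
an ohmic gemmule nicotinic conductance complete the mechanism set. The
integrator (compiled C++) uses Crank–Nicolson voltage updates with a
Hines-ordered tree solve and staggered exponential-Euler gating at
dt = 10 µs.

Nine published conductance presets (`fig2A` … `fig3E`) ship as plain-text
configs together with their current-clamp protocols, and an analysis layer
detects spikes, accommodation, sag and rebound, LTS (via a
sodium-conductance-blocked companion trace) and plateau potentials, and
classifies responses into the phenotype vocabulary.

## Worked example: the low-threshold calcium spike

```r
library(pgcell)
pre  <- load_preset("fig3A")          # LTS with single AP
cell <- build_cell(pre$params)
tr   <- run_current_clamp(cell, stimulus_protocol(10, dur_ms = 600,
                                                  onset_ms = 100, post_ms = 400))
print(tr)
detect_spikes(tr, window = c(100, 700))
blocked <- run_current_clamp(build_cell(apply_pharmacology(pre$params, c(Na = 0))),
                             stimulus_protocol(10, 600, 100, 400))
detect_lts(tr, blocked, window = c(100, 700))
```

prints

```
PG current-clamp trace (LTS-single-AP)
  22001 samples over 1100 ms (dt 0.01 ms, recorded every 5 steps)
  stimulus: 10 pA @ 100-700 ms
  resting potential: -72.84 mV; somatic range [ -78.6 , 18.6 ] mV
spike times (ms): 269.4 293.8
LTS: present=TRUE amplitude=41.2 mV duration=263 ms
```

The 10 pA step slowly charges the cell until the T-type calcium current
regenerates, producing a broad 41 mV depolarizing envelope (the LTS, which
survives setting the fast sodium conductance to zero) crowned by full
sodium spikes. `classify_all()` runs every preset under its published
protocol pair and compares the classified label with the published response
type; `vignette("pgcell-model")` documents the model, its numerical
choices, and which published behaviors this implementation does and does
not reproduce.

A thin command-line front end is included:

```sh
Rscript inst/cli/pgcell.R run --preset fig3A --out lts.tsv
Rscript inst/cli/pgcell.R classify-all
Rscript inst/cli/pgcell.R curves --channel CaT --out cat_curves.tsv
```

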