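# Gated membrane mechanisms of the PG cell model: gating orders (a, b),
# temperature coefficients (phi), kinetics kind per gate and reversal rule.
# Rate/steady-state functions are evaluated in the compiled kinetics core;
# dump_gating_curves() writes them out on a voltage grid for inspection.
channels:
  - name: Na
    a: 3
    b: 1
    phi_m: 0.24
    phi_h: 0.24
    kinetics_m: alpha-beta
    kinetics_h: alpha-beta
    reversal: "+50 mV"
    permeant_ion: Na
  - name: K
    a: 4
    b: 0
    phi_m: 0.24
    phi_h: 0
    kinetics_m: alpha-beta
    kinetics_h: none
    reversal: "-85 mV"
    permeant_ion: K
  - name: KA
    a: 1
    b: 1
    phi_m: 0.46
    phi_h: 0.46
    kinetics_m: steady-state/tau
    kinetics_h: steady-state/tau
    reversal: "-85 mV"
    permeant_ion: K
  - name: KCa
    a: 2
    b: 0
    phi_m: 1.12
    phi_h: 0
    kinetics_m: calcium-dependent
    kinetics_h: none
    reversal: "-85 mV"
    permeant_ion: K
  - name: H
    a: 1
    b: 0
    phi_m: 0.35
    phi_h: 0
    kinetics_m: steady-state/tau
    kinetics_h: none
    reversal: "0 mV"
    permeant_ion: mixed cation
  - name: CaL
    a: 2
    b: 1
    phi_m: 1
    phi_h: 1
    kinetics_m: steady-state/tau
    kinetics_h: instantaneous (calcium-dependent)
    reversal: "calcium Nernst"
    permeant_ion: Ca
  - name: CaT
    a: 2
    b: 1
    phi_m: 0.85
    phi_h: 0.90
    kinetics_m: steady-state/tau
    kinetics_h: steady-state/tau
    reversal: "calcium Nernst"
    permeant_ion: Ca
  - name: CAN
    a: 2
    b: 0
    phi_m: 1.12
    phi_h: 0
    kinetics_m: calcium-dependent
    kinetics_h: none
    reversal: "0 mV"
    permeant_ion: mixed cation
ohmic:
  - name: leak
    reversal: "-70 mV (preset-overridable)"
  - name: nic
    reversal: "+3.2 mV"
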