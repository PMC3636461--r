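key: fig3B
response_type: "LTS with AP burst"
label: LTS-burst
gmax_S_cm2:
  Na: 0.011
  K: 0.075
  KA: 0.025
  KCa: 0
  H: 3.58e-5
  CaL: 0
  CaT: 0.002
  CAN: 0
e_leak_mV: -70
noise: false
nicotinic: false
protocol:
  depol:    {amp_pA: 10,  dur_ms: 600}
  hyperpol: {amp_pA: -10, dur_ms: 600}
  post_ms: 600
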