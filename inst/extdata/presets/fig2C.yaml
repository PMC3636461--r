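key: fig2C
response_type: "Single spike"
label: single-spike
gmax_S_cm2:
  Na: 0.01
  K: 0.002
  KA: 0.02
  KCa: 0
  H: 0
  CaL: 0
  CaT: 2.00e-4
  CAN: 0
e_leak_mV: -70
noise: false
nicotinic: false
protocol:
  depol:    {amp_pA: 25,  dur_ms: 600}
  hyperpol: {amp_pA: -25, dur_ms: 600}
  post_ms: 600
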