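key: fig2B
response_type: "Accommodating simple spike train"
label: accommodating
gmax_S_cm2:
  Na: 0.01
  K: 0.001
  KA: 0.005
  KCa: 0
  H: 0.001
  CaL: 0
  CaT: 4.00e-4
  CAN: 0
e_leak_mV: -70
noise: false
nicotinic: false
protocol:
  depol:    {amp_pA: 22,  dur_ms: 600}
  hyperpol: {amp_pA: -22, dur_ms: 600}
  post_ms: 600
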