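key: fig3C
response_type: "AP burst with extended plateau potential"
label: plateau
gmax_S_cm2:
  Na: 0.004
  K: 0.007
  KA: 0.001
  KCa: 0.001
  H: 0.0005
  CaL: 0.001
  CaT: 0.0001
  CAN: 0.00128
e_leak_mV: -70
noise: false
nicotinic: false
protocol:
  depol:    {amp_pA: 30,  dur_ms: 200}
  hyperpol: {amp_pA: -20, dur_ms: 600}
  post_ms: 3000
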