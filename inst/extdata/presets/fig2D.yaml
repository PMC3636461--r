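key: fig2D
response_type: "Irregular spiking (rare)"
label: irregular
gmax_S_cm2:
  Na: 0.02
  K: 0.01
  KA: 0.01
  KCa: 0
  H: 0.005
  CaL: 0
  CaT: 1.00e-4
  CAN: 0
e_leak_mV: -70
noise: true      # irregular firing requires the colored current noise
nicotinic: false
protocol:
  depol:    {amp_pA: 7.5, dur_ms: 600}
  hyperpol: {amp_pA: -20, dur_ms: 600}
  post_ms: 600
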