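key: fig2A
response_type: "Non-accommodating simple spike train"
label: non-accommodating
gmax_S_cm2:
  Na: 0.02
  K: 0.01
  KA: 0.01
  KCa: 0
  H: 0.002
  CaL: 0
  CaT: 0
  CAN: 0
e_leak_mV: -55    # this phenotype requires a depolarized leak reversal
noise: false
nicotinic: false
protocol:
  depol:    {amp_pA: 3.5,  dur_ms: 600}
  hyperpol: {amp_pA: -1.2, dur_ms: 600}
  post_ms: 600
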