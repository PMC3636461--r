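# Default cell configuration: six-section PG cell geometry, passive
# constants, calcium shell, noise source and nicotinic conductance.
# g_leak is not a free choice: it is calibrated once (see calibrate_leak())
# so the passive cell's somatic input resistance equals target_rin_MOhm.
geometry:
  soma:    {L_um: 8,  diam_um: 8, parent: null,  pos: 0.5}
  dend1:   {L_um: 20, diam_um: 1, parent: soma,  pos: 0.5}
  dend2:   {L_um: 20, diam_um: 1, parent: soma,  pos: 0.5}
  shaft:   {L_um: 1,  diam_um: 1, parent: dend1, pos: 0.5}
  gemmule: {L_um: 1,  diam_um: 1, parent: shaft, pos: 1.0}
  axon:    {L_um: 50, diam_um: 1, parent: soma,  pos: 0.5}
passive:
  cm_uF_cm2: 1.2
  ra_ohm_cm: 173
  e_leak_mV: -70
  g_leak_S_cm2: 2.64901846e-04  # calibrated: passive somatic R_in = 775 MOhm
  target_rin_MOhm: 775
reversals_mV:
  Na: 50
  K: -85
  H: 0
  CAN: 0
  nic: 3.2
calcium:
  basal_mM: 2.4e-4
  tau_decay_ms: 5
  shell_depth_um: 0.1
  external_mM: 2
  temperature_C: 23
noise:
  sd_pA: 0.05          # 50 fA white source, before coloring
  tau_ms: 5            # exponential coloring kernel
  dt_ms: 0.125         # 8 kHz sampling -> 0-4 kHz band
nicotinic:
  g_S_cm2: 0.005
  e_mV: 3.2
  scope: gemmule
d_lambda:
  fraction: 0.1
  frequency_Hz: 100
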