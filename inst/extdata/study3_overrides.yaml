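# Ventilated, sedated patient for intra-breath analysis: pressure-control
# ventilation at PEEP 5 cmH2O, 15 breaths/min, 0.5 s end-inspiratory
# pause, with the cardiovascular and respiratory adjustments of that
# study population. Sections are organisational; keys are global.
respiratory:
  C_L: 0.06
  C_cw: 0.11
  V_u_L: 0.4
  V_u_cw: 1.0
heart:
  E_max_lvf0: 1.9
  k_E_lvf: 0.016
  k_E_rvf: 0.011
  P_0_lvf: 0.8
  P_0_rvf: 1.5
systemic:
  R_sp0: 3.0
  R_ep0: 1.0
control:
  T_0: 0.35
  amp_mus: 0.0
ventilator:
  vent_mode: PCV
  PEEP: 5.0
  support: 15.5
  RR: 15.0
  IE_ratio: 0.5
  end_insp_pause: 0.5
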