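lipid:
  sigma_tail: 0.76
  head_scale: 0.95
  ps_head_scale: 1.0
  core_k: 200.0
  eps_att: 0.85
  w_att: 0.95
  bond_k: 120.0
  bond_r0: 1.05
  bend_k: 8.0
  target_thickness: 5.0
  target_apl: 0.67
protein:
  sigma: 0.2
  epsilon: 1.0
  cutoff: 0.5
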