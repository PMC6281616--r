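# Full-scale system: 100 nm tube, 20 nm outer / ~11 nm lumen diameter,
# 14,500 lipids in a 100 x 50 x 50 nm box; 1e6-step ramp and 1e7-step
# production with dumps every 10,000 tau.
build:
  length: 100
  outer_diameter: 20
  lumen_diameter: 11
  n_lipids: 14500
  ps_fraction: 0.40
  box_yz: 50
protocol:
  timestep: 1
  equil_steps: 1.0e+6
  ramp_start: 10
  ramp_end: 310
  prod_steps: 1.0e+7
  temperature: 310
  damping: 100
  dump_interval: 10000
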