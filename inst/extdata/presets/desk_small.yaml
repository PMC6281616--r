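# Desk-scale system for test-bench runs: 30 nm tube at the same area
# per lipid, 8e3-step ramp and 2.5e4-step production.
build:
  length: 30
  outer_diameter: 13.5
  lumen_diameter: 5.5
  ps_fraction: 0.40
protocol:
  timestep: 1
  equil_steps: 8.0e+3
  ramp_start: 10
  ramp_end: 310
  prod_steps: 2.5e+4
  temperature: 310
  damping: 100
  dump_interval: 1000
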