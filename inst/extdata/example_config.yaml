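# Example configuration: a coarse, fast variant of the cubic skin phantom.
# Any key left out falls back to the package default; unknown keys are
# rejected.
seed: 42
phantom:
  voxel_size_m: 0.0009
  epsilon3: 0.05
vasculature:
  iterations: 500
  root_radius_m: 0.0002
  murray_exponent: 3
flow:
  inlet_flow_ml_s: 0.004
thermal:
  T_inf_C: 23
  q_heat_W_m2: 150
sweep:
  T_amb_C: [20, 22, 24]
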