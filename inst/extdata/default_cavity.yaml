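# Default desk-scale cavity run: regular breathing on the synthetic
# 2D mid-plane cross-section. All physical defaults (fluid density
# 1017.5 kg/m^3, viscosity 0.0012 Pa.s, the breathing presets) are filled
# in by the package's constructors.
mode: cavity
preset: regular
geometry:
  cavity_width: 0.18      # m
  cavity_height: 0.20     # m
  ovary_radius: 0.015     # m
  mesh_size: 0.0065       # m
  dim: 2
solver:
  steps_per_cycle: 80
  max_nonlinear_iterations: 2
  nonlinear_tolerance: 1.0e-4
  sd_constant: 0.5
  snapshot_stride: 4
outputs:
  vtu_stride: 4
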