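# Perfusion-bioreactor rig: 8 radial hydrogel chambers, idealized-cell
# open-channel submodel, target FSS levels 1 / 5 / 11 dynes/cm^2.
# Hydrogel permeability/porosity and the cell/channel dimensions are rig
# configuration; the values below are the package's documented
# placeholders.
mode: bioreactor
bioreactor:
  target_fss: [1, 5, 11]    # dynes/cm^2
  chamber:
    n_chambers: 8
  hydrogel:
    permeability: 1.0e-14   # m^2
    porosity: 0.9
    plug_length: 0.01       # m
    plug_cross_section_area: 2.83e-5   # m^2
  cell:
    cell_radius: 7.5e-6     # m
    channel_height: 1.0e-4  # m
    inlet_speed: 1.0e-4     # m/s (design starting point)
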