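# Example simulation configuration.
# Geometry keys override the default root layout; all lengths in um and
# multiples of spacing_um.  Omitted keys keep their defaults.
geometry:
  spacing_um: 4
  root_length_um: 968
  root_half_width_um: 112
  mz_length_um: 320
  mz_cell_length_um: 8
  ez_cell_lengths_um: [12, 16, 20, 24, 28, 32, 36, 40]
  file_widths_um:
    epidermis: 20
    outer: 32
    pericycle: 20
    vascular: 40
  columella_lengths_um: [16, 16]
  qc_length_um: 8
# parameters: path/to/parameters.yaml   # defaults shipped with the package
genotypes: [wt, pls]
solver:
  maxSteps: 600
outputs: [auxin, CK, ET, PLSp]
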