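name: uexplorer_full_bgo_194
family: crystal
material: BGO
afov: 194.8
n_units: 8
unit_axial_length: 24.35
inter_unit_gap: 0.0
n_blocks_per_ring: 24
n_crystals_axial: 84
n_crystals_transaxial: 35
crystal_transaxial: 0.276
crystal_axial: 0.276
crystal_depth: 1.81
ring_inner_radius: 39.3
packing_fraction: 0.85
energy_acceptance: 0.83
occupancy: full
cut:
  type: ring_difference
  max_ring_difference: 5
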