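name: biograph_vision
family: crystal
material: LSO
afov: 26.3
n_units: 8
unit_axial_length: 3.2
inter_unit_gap: 0.1
n_blocks_per_ring: 38
n_crystals_axial: 10
n_crystals_transaxial: 20
crystal_transaxial: 0.32
crystal_axial: 0.32
crystal_depth: 2.0
ring_inner_radius: 39.3
packing_fraction: 0.85
energy_acceptance: 0.83
occupancy: full
cut:
  type: ring_difference
  max_ring_difference: 37
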