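name: jpet_4l_6x30_200
family: strip
material: plastic
afov: 200.0
n_layers: 4
strip_length: 200.0
strip_width: 0.6
strip_thickness: 3.0
layer_radii:
- 41.5
- 45.5
- 49.5
- 53.5
azimuthal_fill: 0.98
energy_threshold_keV: 200.0
wls_unit_area: 0.18
cut:
  type: acceptance_angle
  theta_AA: 57.0
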