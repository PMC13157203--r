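# Example run configuration: overrides are merged onto package defaults.
seed: 42
geometry:
  n_rows: 19
  n_cols: 19
  pitch_um: 350
  base_um: 300
  tip_height_um_min: 450
  tip_height_um_max: 500
render:
  noise_sd: 2
analysis:
  window_um: [2000, 4000]
dose:
  irradiance_mw_cm2: 125
  duration_s: 1200
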