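# Demo end-to-end run: small phantom, four biopsy targets, full report.
seed: 1
stages: [simulate, relax, perfuse, vsi, histo, validate]
simulate:
  grid: [32, 32, 8]
  voxel_size: [1.875, 1.875, 5.0]
  n_timepoints: 40
  tr_ms: 2000
  echo_times_ms: [14.0, 34.1, 58.0, 92.4]
  noise_sigma: 5
  tumor_leakage: 0.0
  bolus: {t0: 20, alpha: 3, beta: 3.5, recirculation_fraction: 0.15}
  dwi: {b_values: [0, 500, 1000], noise_sigma: 5}
  n_targets: 4
  slide: {image_px: [640, 640], um_per_px: 1.0, vessels_per_slide: 17}
relax:
  smooth: true
perfuse:
  leak_mode: bidirectional
vsi:
  constant_k: 0.867
histo:
  rois: 3
  join_distance_um: 5
  closing_radius_px: 2
  min_lumen_area_px: 10
validate:
  radius_mm: 5
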