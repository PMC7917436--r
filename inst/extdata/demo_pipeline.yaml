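seed: 1
thresholds:
  in_max: 4.0
  out_min: 5.0
pca:
  variance_target: 0.9
clustering:
  min_cluster_size_frac: 0.02
  min_population: 0.01
representatives: 25
spectra:
  temperature: 300
  broadening: 100
  shift: -3500
variants:
  - name: crowded
    simulate:
      n_frames: 800
      frame_spacing: 1
    crowding:
      n_frames: 100
      separation: 3.5
      ring_jitter_sd: 0.3
  - name: loose
    simulate:
      n_frames: 800
      frame_spacing: 1
      energy_model:
        IN:  {exc_mean: 3.22, exc_sd: 0.02, emi_mean: 2.8088, emi_sd: 0.02}
        OUT: {exc_mean: 3.27, exc_sd: 0.02, emi_mean: 2.8688, emi_sd: 0.02}
    crowding:
      n_frames: 100
      separation: 5.0
      ring_jitter_sd: 0.6
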