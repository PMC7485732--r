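# Desk-scale example configuration for `cortexage` (run_pipeline / CLI).
# Any omitted field falls back to the package defaults.
cohort:
  n: 8
  age_range: [19, 71]
  seed: 42
geometry:
  dim: 48
  voxel_mm: 2
  semi_axes_mm: [32, 40, 32]
  ventricle_semi_axes_mm: [5, 9, 5]
protocol:
  snr: 50
  noise_model: gaussian
  bias_amplitude: 0.1
anatomy:
  oracle_ribbon: true
stats:
  fwhm_mm: 10
  n_perm: 200
  threshold_p: 0.05
  alpha: 0.05
  mapwise_parameters: [T2prime]
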