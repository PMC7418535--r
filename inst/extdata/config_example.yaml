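# Example pipeline configuration: a reduced-size run of the full chain.
# Every threshold the analysis applies is set here; unknown keys are
# rejected at load time.
seed: 1
simulate:
  n_subjects: 3
  intra_module_corr: 0.5
  inter_module_corr: 0.1
  n_runs: 2
  scans_per_run: 600
  repetition_time: 0.72
  n_whole_brain: 128
  ar_coef: 0.3
  spikes_per_run: 3
  spike_size: 1.0
preprocess:
  fd_threshold: 0.5          # mm
  bandpass_low: 0.01         # Hz
  bandpass_high: 0.08        # Hz
netbuild:
  density: 0.05
  rule: union
graphmetrics:
  n_restarts: 500
  n_perm: 500
  n_rand: 500
behavior:
  n_subjects: 32
  coupling_rho: 0.4
  trials_per_mixture: 15
  n_perm: 2000
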