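# Example pipeline configuration (see readPipelineConfig()).
schema_version: 1
seed: 42
mcmc_draws: 2000
log_level: info
input:
  mode: synthetic
  n_reports: 10000
thresholds:
  min_count: 10
  min_lift: 2
  dsr_ror: 5
  dsr_ratio: 10
  bh_alpha: 0.05
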