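pipeline: functional
seed: 42
cohort:
  n_per_group: 4
  n_timepoints: 300
  hypo_cluster1_loading: 0.3
ica:
  n_components: 12
cluster:
  k: 4
compare:
  alpha: 0.05
  test: t
seedmap:
  component: 1
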