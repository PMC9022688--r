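pipeline: structural
seed: 42
structural:
  n_per_group: 3
  hypo_lambda_perp: 0.00045
  n_samples: 10
  n_regions: 12
  density: 0.2
  alpha: 0.05
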