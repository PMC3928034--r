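# Example analysis configuration for run_pipeline().
# Unspecified fields keep the defaults of default_config().
seed: 42
sim:
  locus_length: 4.0e6
  n_vk_functional: 60
  n_vk_pseudo: 40
thresholds:
  min_fragment_length: 100
  fold: 1.5
  evidence: 25
fish:
  n_nuclei: 120
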