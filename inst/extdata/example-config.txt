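# Example pipeline configuration (flat key: value; see read_run_config()).
# Values omitted here keep their defaults from default_config().
outdir: pagephen-out
seed: 42
n_per_class: 3
n_days: 730
threshold_consistency: 0.5
threshold_single: 0.5
threshold_double: 0.3
n_langs: 30
coupling: 0.8
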