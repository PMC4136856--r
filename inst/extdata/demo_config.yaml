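# Small demonstration configuration for run_pipeline(); any block omitted
# here keeps its default from default_pipeline_config().
seed: 1
landscape:
  n_rows: 60
  n_cols: 60
survey:
  n_sites: 100
  n_occasions: 6
  min_spacing: 300
model:
  n_starts: 1
circuit:
  n_perimeter_nodes: 8
  pair_subsample: 6
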