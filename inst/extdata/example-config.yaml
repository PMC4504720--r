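# Example pipeline configuration: simulate a two-interval FTL experiment
# (6.1 and 5.5 cM, moderate interference) plus a 50-cell chiasma sample,
# then run the full tetrad / chiasma analysis.
seed: 42
simulate:
  marker_positions_cM: [0.0, 6.1, 11.6]
  interference_shape: 5
  class2_fraction: 0.15
  n_tetrads: 2000
  n_cells: 50
analysis:
  coc_definition: tetrad
  gof_mode: pooled
  range: [6, 8]
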