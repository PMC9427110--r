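# Example pipeline configuration for `stitchforge run --config ...`
# or run_pipeline("pipeline-example.yaml") from R.
seed: 5
generate:
  rows: 4
  cols: 4
  tile_size: 256
  n_sections: 3
  featureless_tile_frac: 0.05
lens:
  # radial distortion with ~12 px corner displacement at this tile size
  k1: 2.0e-6
  rows: 3
  cols: 3
  overlap_frac: 0.5
  grid_n: 6
montage:
  optimize: true
align3d:
  z_window: 3
  grid_nodes: 25
render:
  scale: 0.25
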