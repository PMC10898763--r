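# Demo run configuration: a 60-participant study on a 2 x 2 km synthetic
# city. Keys mirror the run_config()/world_config() arguments; anything
# omitted keeps its package default.
world:
  extent_m: [2000, 2000]
  cell_size_m: 10
  n_participants: 60
  n_days: 2
calibration:
  slope: 1.05
  intercept: -0.5
selector: adj_r2
seed: 23
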