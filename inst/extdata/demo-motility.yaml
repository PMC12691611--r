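# Demo: simulate a small wild-type-like movie, track it, and quantify
# velocities and surface coverage. Scaled down for a quick run.
stage: chain
outdir: mxquant-demo
seed: 1
params:
  arena_width: 80
  arena_height: 80
  pixel_size: 0.4
  n_cells: 15
  duration: 500
  frame_interval: 10
  speed_mean: 10.36
  speed_sd: 5.03
  noise_sd: 0.03
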