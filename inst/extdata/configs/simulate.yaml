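# orchardsar simulate: image a point-scatterer scene
scene: inst/extdata/example_scene.json
out_dir: results/sim
radar:
  f_min: 3.2e10
  f_max: 3.7e10
  n_freq: 64
  R0: 0.5
aperture:
  nx: 64
  ny: 64
  dx: 0.004
  dy: 0.005
pad: 2
# snr_db: 20   # uncomment to add receiver noise
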