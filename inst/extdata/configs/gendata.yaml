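# orchardsar gendata: render a labelled synthetic orchard dataset
out_dir: results/dataset
split_ratio: 0.7
mode: fast
orchard:
  n_images: 260
  image_size: 128
  apples_per_image: [2, 5]
  occlusion_fraction: 0.3
  speckle_looks: 4
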