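# orchardsar train: fit the detector on a generated dataset
data_dir: results/dataset
out_dir: results/run
epochs: 10
batch_size: 8
lr: 3.0e-3
warmup: 30
schedule: cosine
augment: true
verbose: true
detector:
  fusion_width: 32
  rfn_iterations: 2
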