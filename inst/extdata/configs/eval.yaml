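# orchardsar eval: score a checkpoint on the test split
data_dir: results/dataset
checkpoint: results/run/detector.ckpt
out_dir: results/run
split: test
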