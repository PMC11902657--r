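[{"x":0.02,"y":-0.03,"z":0.04,"amp_re":1,"amp_im":0},{"x":-0.03,"y":0.01,"z":-0.02,"amp_re":0.8,"amp_im":0},{"x":0,"y":0.04,"z":0,"amp_re":0.6,"amp_im":0}]
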