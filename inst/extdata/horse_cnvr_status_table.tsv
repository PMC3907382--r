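status	n_cnvrs	total_bp
gain	109	5005156
loss	234	7924489
both	10	656914
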