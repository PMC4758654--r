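# Full model: angiogenic switch experiment to day 5.1.
mode: vascular
t_end_days: 5.1
seed: 1
nx: 512
ny: 396
record_every: 1
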