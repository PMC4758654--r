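# Avascular control: capillary and TAF dynamics frozen, no TEC activation,
# S = 1 throughout. Long-horizon regression experiment.
mode: avascular
t_end_days: 1054.0
seed: 1
nx: 512
ny: 396
record_every: 5
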