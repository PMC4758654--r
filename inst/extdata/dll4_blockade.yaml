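# Dll4/Notch down-regulation: TECs may activate closer together
# (delta4 = 55 instead of 80), producing a denser but less functional network.
mode: dll4_blockade
delta4_override: 55.0
t_end_days: 5.1
seed: 1
nx: 512
ny: 396
record_every: 1
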