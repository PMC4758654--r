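# Small-spheroid variant: initial tumor three times smaller than the default,
# used to study the fate of the necrotic core after vascularization.
mode: small_spheroid
t_end_days: 5.1
seed: 1
nx: 512
ny: 396
record_every: 1
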