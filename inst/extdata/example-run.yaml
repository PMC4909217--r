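# Example assembly run: 128 ULFs at an equivalent vimentin concentration of
# 17.8 g/l, stopping at a mean filament length of 5 ULFs.
n0: 128
concentration_gl: 17.8
max_bond_angle: 15
target_mean_ulf: 5
max_sweeps: 10000000
record_every: 250000
seed: 1
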