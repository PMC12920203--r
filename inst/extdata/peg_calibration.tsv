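peg_percent	water_potential_mpa
0	-0.72
12	-0.98
24	-1.67
32	-2.26
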