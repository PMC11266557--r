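genotype	wt	het	hom
0|0	120	4	1
0|1	0	116	1
1|1	0	0	39
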