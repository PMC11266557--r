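genotype	wt	het	hom
0|0	68	0	0
0|1	2	52	0
1|1	0	0	11
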