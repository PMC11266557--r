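genotype	wt	het	hom
6|6	78	1	0
5|6	1	28	2
5|5	0	0	3
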