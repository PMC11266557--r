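genotype	wt	het	hom
6|6	372	9	0
5|6	1	178	0
5|5	0	13	16
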