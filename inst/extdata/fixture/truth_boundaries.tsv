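boundary_id	gene_id	chrom	strand	intron_start	intron_end	truth_p	truth_eps
chrS1:795:1595:-	g001	chrS1	-	795	1595	0.5	0.05
chrS1:3379:3465:-	g003	chrS1	-	3379	3465	0	0.05
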