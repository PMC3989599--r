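chrS1	irquant	exon	501	795	.	-	.	gene_id "g001"; transcript_id "g001.t1";
chrS1	irquant	exon	1596	1858	.	-	.	gene_id "g001"; transcript_id "g001.t1";
chrS1	irquant	exon	2359	2640	.	-	.	gene_id "g002"; transcript_id "g002.t1";
chrS1	irquant	exon	3141	3379	.	-	.	gene_id "g003"; transcript_id "g003.t1";
chrS1	irquant	exon	3466	3762	.	-	.	gene_id "g003"; transcript_id "g003.t1";
chrS1	irquant	exon	896	1045	.	+	.	gene_id "gNest"; transcript_id "gNest.t1";
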