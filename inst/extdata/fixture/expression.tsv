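gene_id	expr_0_2	expr_2_4
g001	376.73	177.2
g002	1.54	38.93
g003	9.1	0.48
gNest	362.86	63.87
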