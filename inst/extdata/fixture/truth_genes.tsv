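gene_id	gene_class
g001	maternal
g002	early_zygotic
g003	unclassified
gNest	maternal
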