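gene_id	lca
G01	1
G02	3
G03	2
G04	5
G05	8
G06	12
G07	15
G08	18
G09	20
G10	22
G11	25
G12	30
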