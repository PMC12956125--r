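gene_id	label
G01	1
G02	1
G03	1
G04	1
G05	0
G06	0
G07	0
G08	0
G09	0
G10	0
G11	0
G12	0
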