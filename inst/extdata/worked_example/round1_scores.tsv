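gene_id	score
G01	0.95
G02	0.9
G03	0.8
G04	0.6
G05	0.85
G06	0.55
G07	0.5
G08	0.4
G09	0.35
G10	0.3
G11	0.2
G12	0.1
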