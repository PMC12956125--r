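gene_id	target
G01	1
G02	1
G03	1
G04	1
G05	0.6666666666666666
G06	0.6666666666666666
G07	0.5714285714285714
G08	0.5
G09	0.4444444444444444
G10	0.4
G11	0.36363636363636365
G12	0.3333333333333333
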