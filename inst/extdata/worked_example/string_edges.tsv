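protein1	protein2	combined_score
G01	G02	900
G01	G03	700
G02	G03	650
G01	G04	550
G02	G05	500
G03	G06	400
G01	G01	999
G02	G01	800
G05	G10	720
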