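gene_id	kind	score
G01	missense	0.2
G01	missense	0.4
G01	missense	0.6
G01	nonsense	0.8
G02	missense	0.7
G02	nonsense	0.6
G02	nonsense	0.8
G03	missense	0.5
G03	nonsense	0.9
G04	missense	0.6
G04	nonsense	0.5
G05	missense	0.4
G05	nonsense	0.4
G06	missense	0.2
G06	nonsense	0.1
G07	missense	0.3
G07	nonsense	0.2
G08	missense	0.1
G08	nonsense	0.3
G09	missense	0.2
G09	nonsense	0.2
G10	missense	0.1
G10	nonsense	0.1
G11	missense	0.3
G11	nonsense	0.1
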