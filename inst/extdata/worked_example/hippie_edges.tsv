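idA	idB	confidence
G01	G02	0.9
G01	G06	0.7
G04	G05	0.6
G07	G08	0.5
G09	G10	0.4
G02	G04	0.8
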