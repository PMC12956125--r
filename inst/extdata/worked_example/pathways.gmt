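T1	enriched synthetic pathway	G01	G02	G03	G04	G05
T2	synthetic pathway	G01	G06	G07
T3	synthetic pathway	G08	G09
T4	synthetic pathway	G02	G05	G10
T5	synthetic singleton	G11
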