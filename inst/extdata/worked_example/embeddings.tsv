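gene_id	emb_001	emb_002	emb_003	emb_004
G01	0.9	0.1	-0.2	0.5
G02	0.8	0.2	-0.1	0.4
G03	0.7	0.0	-0.3	0.6
G04	0.6	0.3	0.0	0.3
G05	0.5	-0.1	0.1	0.2
G06	0.1	0.4	0.2	-0.2
G07	0.0	0.5	0.3	-0.1
G08	-0.1	0.2	0.4	-0.3
G09	-0.2	0.1	0.5	-0.4
G10	-0.3	0.0	0.2	-0.5
G11	-0.4	-0.2	0.1	-0.6
G12	-0.5	-0.3	0.0	-0.7
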