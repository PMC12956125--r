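feature_id	n1	n2	T1	T2	U1	U2	mu_u	sigma_corr	z1	z2
T1	4	8	40	38	30	2	16	5.04524979109513	2.7748873851023217	-2.7748873851023217
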