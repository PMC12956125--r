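auc	aupr	ef_at_3	max_ef_at_3
0.9375	0.8875	2	3
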