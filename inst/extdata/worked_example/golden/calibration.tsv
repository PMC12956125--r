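threshold	n_above	n_pos_above	precision
0.1	12	4	0.3333333333333333
0.2	11	4	0.36363636363636365
0.3	10	4	0.4
0.35	9	4	0.4444444444444444
0.4	8	4	0.5
0.5	7	4	0.5714285714285714
0.55	6	4	0.6666666666666666
0.6	5	4	0.8
0.8	4	3	0.75
0.85	3	2	0.6666666666666666
0.9	2	2	1
0.95	1	1	1
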