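isoform	root_1	root_2	leaf_1	leaf_2	peg_1	peg_2
g1.t1	12.1	9.8	11.0	10.2	13.5	12.9
g1.t2	0	0	0	0	8.4	9.1
g2.t1	5.2	4.9	0	0	0	0
g2.t2	1.1	1.4	2.0	1.8	1.6	1.2
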