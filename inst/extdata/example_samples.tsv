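sample	group
root_1	root
root_2	root
leaf_1	leaf
leaf_2	leaf
peg_1	peg
peg_2	peg
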