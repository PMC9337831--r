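chain	resnum	icode	critical	note
A	619		1	catalytic lysine
A	741		1	DFG aspartate
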