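chain	resnum	icode	resname	critical	backbone_mediated	inhibitor_mean	natural_mean	low_contact	note
A	591		LYS	0	1	2.5	1	0	
A	593		LEU	0	0	5.8	2.1	0	
A	594		GLY	0	1	1.5	1.2	0	
A	596		GLY	0	1	1.2	1.5	0	
A	597		GLU	0	1	1	0.8	0	
A	601		VAL	0	0	2	2.5	0	
A	617		ALA	0	0	1.1	1.8	0	
A	619		LYS	1	0	3	3.5	0	
A	637		GLU	0	0	0.4	0.1	1	
A	650		ILE	0	0	6.2	4	0	
A	669		VAL	0	0	0.6	0.2	1	
A	671		LEU	0	0	4.9	3	0	
A	672		PRO	0	1	2.1	1.1	0	
A	673		PHE	0	1	3.3	2.2	0	
A	674		MET	0	1	2.8	2	0	
A	677		GLY	0	1	1.4	0.9	0	
A	681		THR	0	1	1	0.6	0	
A	730		MET	0	0	2.2	2.2	0	
A	741		ASP	1	0	2	2.6	0	
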