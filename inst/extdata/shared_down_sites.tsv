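protein	gene	position	residue	sequence_window	tmd8_rep1	tmd8_rep2	u2932_rep1	u2932_rep2
Inositol 1,4,5-trisphosphate 3-kinase B	ITPKB	43	S	PRRAVLSPGSVFS	0.41	0.48	0.57	0.58
Golgi vesicular membrane-trafficking protein p18	BET1	50	S	TAIKSLSIEIGHE	0.29	0.50	0.57	0.61
Vesicle-associated membrane protein-associated protein B/C	VAPB	158	S	IVSKSLSSSLDDT	0.44	0.54	0.66	0.60
Extracellular signal-regulated kinase 2	MAPK1	187	Y	TGFLTEYVATRWY	0.34	0.47	0.23	0.41
Beta-adrenergic receptor kinase 1	ADRBK1	685	S	PLVQRGSANGL_	0.54	0.38	0.61	0.64
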