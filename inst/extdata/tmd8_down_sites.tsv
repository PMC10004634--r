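protein	gene	position	residue	sequence_window	tmd8_rep1	tmd8_rep2	u2932_rep1	u2932_rep2
Extracellular signal-regulated kinase 1	MAPK3	204	Y	TGFLTEYVATRWY	0.26	0.42	-	-
Proto-oncogene c-RAF kinase	RAF1	1055	S	ACTLTTSPRLPVF	0.61	0.61	-	-
90 kDa ribosomal protein S6 kinase 1 (RSK1)	RPS6KA1	741	S	RVRKLPSTTL_	0.61	0.59	1.16	0.87
Serine/threonine-protein kinase D2 (PKD2)	PRKD2	214	S	RLGTSESLPCTAE	0.46	0.48	-	-
Serine/threonine-protein kinase D2 (PKD2)	PRKD2	206	S	SLASGHSVRLGTS	0.32	0.48	0.86	0.83
Serine/threonine-protein kinase D2 (PKD2)	PRKD2	710	S	EKSFRRSVVGTPA	0.45	0.56	0.90	0.77
PKCnu (PKD3)	PRKD3	735	S	EKSFRRSVVGTPA	0.41	0.43	0.85	0.77
Serine/threonine-protein kinase TAO1	TAOK1	9	S	STNRAGSLKDPEI	0.65	0.43	1.06	0.57
Lymphocyte-oriented kinase	LOK	13	S	RRILRLSTFEKRK	0.48	0.60	0.85	0.77
Sugen kinase 223	SGK223	889	S	EKAFKGSGHWLPA	0.48	0.47	-	-
Serine/threonine-protein kinase QSK	SIK3	808	S	PLSKQLSADSAEA	0.47	0.55	1.07	0.97
Receptor-interacting serine/threonine-protein kinase 2	RIPK2	531	S	VVSRSPSLNLLQN	0.54	0.59	1.03	0.75
Activating transcription factor 2	ATF2	69	T	VIVADQTPTPTRF	0.53	0.53	-	-
Activating transcription factor 2	ATF2	71	T	VADQTPTPTRFLK	0.50	0.53	0.99	0.86
ETS domain-containing protein Elk-1	ELK1	501	S	STPVVLSPGPQKP	0.33	0.48	-	-
ETS domain-containing transcription factor ERF	ERF	327	S	VYNYHLSPRAFLH	0.59	0.50	-	-
ETS translocation variant 3	ETV3	245	S	MYPDPHSPFAVSP	0.30	0.28	-	-
ETS translocation variant 3	ETV3	250	S	HSPFAVSPIPGRG	0.30	0.28	-	-
Myb-like protein 2	BMYB	487	T	QKVVVTTPLHRDK	0.67	0.50	-	-
Transcription factor RelB	RELB	37	S	ELGALGSPDLSSL	0.68	0.59	0.93	0.87
Nuclear factor of activated T-cells, cytoplasmic 2	NFATC2	759	S	QRSKSLSPSLLGY	0.67	0.61	1.14	1.19
Nuclear factor of activated T-cells, cytoplasmic 2	NFATC2	243	S	PVPRPASRSSSPG	0.65	0.59	-	-
Mitogen-activated protein kinase kinase kinase 7-interacting protein 2 (TAB2)	TAB2	450	S	GNNSATSPRVVVT	0.61	0.66	1.05	0.98
L-plastin	LCP1	5	S	_MARGSVSDEEM	0.52	0.52	0.90	0.88
Nuclear cap-binding protein subunit 1	NCBP	22	S	HKRRKTSDANETE	0.49	0.50	-	1.04
B-cell adapter for phosphoinositide 3-kinase	BCAP	570	Y	ERPGNFYVSSESI	0.51	0.41	-	-
Astrocytic phosphoprotein PEA-15	PEA15	137	S	DIIRQPSEEEIIK	0.35	0.29	1.18	1.03
Sodium/hydrogen exchanger 1	NHE1	703	S	SRARIGSDPLAYE	0.55	0.51	-	-
Heat shock 27 kDa protein	HSP27	82	S	ALSRQLSSGVSEI	0.62	0.60	1.09	0.76
Nuclease-sensitive element-binding protein 1 (YB-1)	YBX1	102	S	PRKYLRSVGDGET	0.60	0.46	-	-
40 kDa proline-rich AKT substrate (PRAS40)	AKT1S1	246	T	PRPRLNTSDFQKL	0.61	0.51	0.84	0.87
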