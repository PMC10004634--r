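kinase	tirabrutinib_ic50	tirabrutinib_fold	ibrutinib_ic50	ibrutinib_fold	acalabrutinib_ic50	acalabrutinib_fold	zanubrutinib_ic50	zanubrutinib_fold
BTK	2.78	1	0.256	1	4.95	1	0.285	1
FYN	2220	799	55.0	215	>10000	>2020	1659	5821
LYNa	3490	1255	17.8	70	>10000	>2020	734	2575
LCK	788	283	5.87	23	5204	1051	369	1293
BLK	1280	460	0.155	0.6	2270	459	1.71	6
BMX	3.16	1	0.747	3	45.1	9	1.26	4
EGFR	>10000	>3597	1.71	7	>10000	>2020	10.7	38
ERBB2	8610	3097	3.01	12	370	75	34.8	122
ERBB4	177	64	0.325	1	30.1	6	2.63	9
ITK	>10000	>3597	21.9	86	>10000	>2020	346	1214
JAK3	>10000	>3597	14.5	57	>10000	>2020	811	2846
TXK	54.5	20	4.89	19	273	55	4.59	16
TEC	9.92	4	1.37	5	13.9	3	4.47	16
CSK	449	162	10.7	42	6653	1344	194	680
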