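probe_id	gene	Se	Sc	fold	score
210798_x	MASP2	116	0	26.61	5.88
208088_s	CFHR5	110	1	95.56	5.41
1554459_s	CFHR3	116	5	103.31	4.77
37020	CRP	110	18	228.26	4.53
210049	SERPINC1	117	18	213.02	4.53
205754	F2	117	13	135.57	4.47
207406	CYP7A1	56	1	19.52	4.43
207097_s	SLC17A2	117	6	45.67	4.34
207874_s	CFHR4	115	18	138.54	4.33
207027	HGFAC	112	4	22.37	4.18
220224	HAO1	117	18	86.38	4.14
231703_s	ADH4	89	3	18.26	4.12
224243	APOA5	109	3	14.26	4.10
207256	MBL2	117	18	74.97	4.07
219903_s	CYP2C8	61	1	7.03	4.02
1557226_a	ASPG	95	2	8.27	3.98
231702	TDO2	84	3	13.10	3.95
231662	ARG1	102	14	40.21	3.85
210326	AGXT	117	8	14.95	3.73
237765	C14orf68	117	13	23.52	3.71
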