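probe_id	gene	Se	Sc	fold	score
205914_s	GRIN1	284	0	4.54	4.69
236324	MBP	211	0	5.13	4.62
238061	LGI3	536	1	14.77	4.48
205989_s	MOG	569	2	24.03	4.42
206899	NTSR2	380	1	16.49	4.38
203540	GFAP	604	14	115.10	4.28
244113	-	595	3	24.55	4.27
231489_x	-	551	18	94.24	4.04
206970	CNTN2	407	1	6.67	4.02
224536_s	PCDHGC5	68	0	3.37	3.94
1556877	-	364	1	5.48	3.88
235375_x	TTC9B	408	3	13.64	3.85
208320	CABP1	365	5	18.23	3.71
230255	GABRD	451	8	23.42	3.70
235794	MOBP	596	12	25.64	3.69
206678	GABRA1	532	15	35.05	3.68
233471	PTPN5	350	2	5.52	3.57
1557481_a	C21orf131	474	3	5.92	3.55
219642_s	PEX5L	415	6	12.91	3.53
232409_x	FBXL16	227	3	11.70	3.53
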