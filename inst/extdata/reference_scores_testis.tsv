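probe_id	gene	Se	Sc	fold	score
1554981	C9orf11	19	0	71.87	6.05
207736_s	TNP2	18	0	52.45	5.89
231563	-	19	0	49.40	5.88
237319	C2orf53	14	0	36.33	5.62
1552395	TSSK3	17	0	22.10	5.49
1562864	-	15	0	22.90	5.45
243494	-	19	0	15.59	5.38
243143	FAM24A	18	0	15.27	5.35
231362	-	19	0	14.14	5.34
1560494_a	CPXCR1	17	0	14.38	5.30
236661	IQCF6	18	0	12.53	5.26
220498	ACTL7B	18	0	11.49	5.23
1556740	-	12	0	16.70	5.21
1554368	NT5C1B	19	1	99.85	5.19
241527	-	16	0	11.57	5.18
1561704	-	11	0	16.40	5.17
241518	-	11	0	16.11	5.16
242925	RNF148	19	1	91.88	5.15
1554855	PARK2	10	0	16.74	5.13
1556207_a	-	17	0	8.65	5.08
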