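tissue	ne	nc	theta	min_se	max_sc
brain	616	2352	1.00	62	24
liver	117	2851	1.00	23	29
testis	36	2932	1.00	7	29
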