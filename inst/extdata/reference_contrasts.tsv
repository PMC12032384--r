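channel	phase	experiment	t	df	n	g_printed
hpr	learning	1	3.51	36	37	0.56
hpr	recall	1	2.48	36	37	0.40
hpr	learning	2	4.56	32	33	0.78
hpr	recall	2	3.26	32	33	0.55
psr_rf5	learning	1	2.15	33	34	0.36
rar	learning	2	1.98	32	33	0.34
scr	recall	2	-1.67	32	33	-0.28
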