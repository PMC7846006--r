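position	ref	alt	total_snps	young_nl_carriers	young_nl_pct	old_nl_carriers	old_nl_pct	old_amd_carriers	old_amd_pct
1120	C	T	219	82	98.8	64	97.0	73	100.0
1284	T	C	218	82	98.8	64	97.0	72	98.6
1556	C	T	218	82	98.8	64	97.0	72	98.6
4104	A	G	187	82	98.8	50	75.8	55	75.3
4556	C	T	0	0	0.0	0	0.0	0	0.0
5320	C	T	185	78	93.4	51	77.3	56	76.7
5471	G	A	170	78	93.4	44	66.7	48	65.8
5474	A	G	170	78	93.4	44	66.7	48	65.8
5498	A	G	156	74	89.2	37	56.1	45	61.6
5840	C	T	194	77	92.8	54	81.8	63	86.3
6023	G	A	198	78	94.0	55	83.3	65	89.0
7146	A	G	197	78	94.0	56	81.8	63	86.3
7256	C	T	216	81	97.6	64	97.0	71	97.2
9075	C	T	198	78	94.0	55	83.3	65	89.0
9168	C	T	196	78	94.0	54	81.8	64	87.7
9254	A	G	192	78	94.0	51	77.3	63	86.3
9629	A	G	192	78	94.0	52	77.3	62	84.9
11914	G	A	188	75	90.4	51	77.3	62	84.9
12705	C	T	182	69	83.1	50	75.8	63	86.3
13095	T	C	165	56	67.5	47	71.2	62	84.9
13105	A	G	166	57	68.7	46	69.7	63	86.3
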