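position	ref	alt	s1_blood	s1_rpe_choroid	s1_retina	s2_blood	s2_rpe_choroid	s2_retina	s3_blood	s3_rpe_choroid	s3_retina	note
73	A	G	99.29	99.73	99.81	NA	NA	NA	99.68	99.79	99.81	73A = H Haplogroup Defining (R0)
152	T	C	NA	NA	NA	NA	NA	NA	99.69	99.78	99.76	NA
195	T	C	NA	NA	NA	NA	NA	NA	99.57	99.68	99.73	NA
199	T	C	98.25	98.90	99.29	NA	NA	NA	NA	NA	NA	NA
203	G	A	98.51	99.16	99.54	NA	NA	NA	NA	NA	NA	NA
204	T	C	99.04	98.13	99.01	NA	NA	NA	NA	NA	NA	NA
217	T	C	NA	NA	NA	NA	NA	NA	99.53	98.25	97.01	NA
263	A	G	NA	NA	NA	99.81	99.82	99.82	99.77	99.75	99.80	NA
508	A	G	NA	NA	NA	NA	NA	NA	99.70	99.70	99.79	NA
1719	G	A	99.43	99.51	99.70	NA	NA	NA	NA	NA	NA	NA
1811	A	G	NA	NA	NA	NA	NA	NA	97.82	99.12	99.44	NA
2706	A	G	99.68	99.79	99.84	NA	NA	NA	99.77	99.76	99.78	2706A = H Haplogroup Defining
3447	A	G	99.38	99.70	99.79	NA	NA	NA	NA	NA	NA	NA
3720	A	G	NA	NA	NA	NA	NA	NA	99.75	99.71	99.81	NA
3849	G	A	NA	NA	NA	NA	NA	NA	99.70	99.73	99.73	NA
3990	C	T	98.66	99.17	99.03	NA	NA	NA	NA	NA	NA	NA
4529	A	T	98.60	99.12	99.12	NA	NA	NA	NA	NA	NA	NA
4553	T	C	NA	NA	NA	NA	NA	NA	90.03	98.53	98.96	NA
4736	T	C	NA	NA	NA	NA	NA	NA	99.81	99.74	99.81	NA
4793	A	G	NA	NA	NA	97.73	99.37	99.08	NA	NA	NA	NA
5348	C	T	NA	NA	NA	97.72	99.36	99.05	NA	NA	NA	NA
5390	A	G	NA	NA	NA	NA	NA	NA	92.42	98.88	99.22	NA
5426	T	C	NA	NA	NA	NA	NA	NA	99.68	99.74	99.77	NA
6045	C	T	NA	NA	NA	NA	NA	NA	89.53	98.48	98.98	NA
6152	T	C	NA	NA	NA	NA	NA	NA	89.66	98.62	98.83	NA
6734	G	A	98.38	99.37	99.38	NA	NA	NA	NA	NA	NA	NA
7028	C	T	99.13	99.45	99.60	NA	NA	NA	95.95	99.25	99.41	7028C = H Haplogroup Defining
8251	G	A	98.38	99.29	99.26	NA	NA	NA	NA	NA	NA	NA
8473	T	C	NA	NA	NA	NA	NA	NA	90.96	98.73	99.18	NA
9947	G	A	99.48	99.63	99.70	NA	NA	NA	NA	NA	NA	NA
10034	T	C	99.73	99.76	99.84	NA	NA	NA	NA	NA	NA	NA
10238	T	C	99.70	99.71	99.84	NA	NA	NA	NA	NA	NA	NA
10398	A	G	99.68	99.86	99.90	NA	NA	NA	NA	NA	NA	NA
10876	A	G	NA	NA	NA	NA	NA	NA	99.05	99.60	99.75	NA
10915	T	C	99.73	99.75	99.82	NA	NA	NA	NA	NA	NA	NA
11467	A	G	NA	NA	NA	NA	NA	NA	98.78	99.66	99.75	NA
11719	G	A	99.37	99.66	99.71	NA	NA	NA	99.63	99.51	99.66	11719G = H Haplogroup Defining (R0)
12308	A	G	NA	NA	NA	NA	NA	NA	99.74	99.77	99.81	NA
12372	G	A	NA	NA	NA	NA	NA	NA	99.68	99.63	99.71	NA
12501	G	A	97.98	99.16	99.16	NA	NA	NA	NA	NA	NA	NA
12557	C	T	NA	NA	NA	NA	NA	NA	89.93	98.32	98.91	NA
12705	C	T	99.12	99.59	99.71	NA	NA	NA	NA	NA	NA	NA
13020	T	C	NA	NA	NA	NA	NA	NA	89.55	98.46	98.92	NA
13734	T	C	NA	NA	NA	NA	NA	NA	99.75	99.70	99.80	NA
13780	A	G	99.45	99.58	99.67	NA	NA	NA	NA	NA	NA	NA
14182	T	C	99.72	99.72	99.75	NA	NA	NA	NA	NA	NA	NA
14766	C	T	99.62	99.76	99.79	NA	NA	NA	99.71	99.73	99.75	14766C = H Haplogroup Defining (HV)
15043	G	A	99.40	99.60	99.67	NA	NA	NA	NA	NA	NA	NA
15907	A	G	NA	NA	NA	NA	NA	NA	99.76	99.78	99.81	NA
15924	A	G	99.74	99.75	99.77	NA	NA	NA	NA	NA	NA	NA
16051	A	G	NA	NA	NA	NA	NA	NA	99.65	99.57	99.73	NA
16129	G	A	99.13	95.51	92.08	NA	NA	NA	NA	NA	NA	NA
16129	G	C	NA	NA	NA	NA	NA	NA	99.56	99.58	99.58	NA
16172	T	C	99.64	99.63	99.79	NA	NA	NA	NA	NA	NA	NA
16189	T	C	NA	NA	NA	NA	NA	NA	97.23	96.55	97.61	NA
16223	C	T	99.28	99.45	99.66	NA	NA	NA	NA	NA	NA	NA
16311	T	C	99.64	99.35	99.70	NA	NA	NA	NA	NA	NA	NA
16362	T	C	NA	NA	NA	NA	NA	NA	99.54	99.60	99.70	NA
16391	G	A	99.19	99.22	99.48	NA	NA	NA	NA	NA	NA	NA
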