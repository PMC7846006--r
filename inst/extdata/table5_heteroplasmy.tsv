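position	ref	alt	s1_blood	s1_rpe_choroid	s1_retina	s2_blood	s2_rpe_choroid	s2_retina	s3_blood	s3_rpe_choroid	s3_retina
64	C	T	NA	NA	NA	NA	1.21	NA	NA	NA	NA
72	T	C	NA	NA	NA	NA	5.22	8.62	NA	NA	NA
76	C	T	NA	3.60	1.80	NA	NA	NA	NA	NA	NA
189	A	G	NA	NA	NA	NA	NA	NA	NA	1.41	1.56
309	C	T	4.86	2.90	3.37	3.36	3.47	3.40	NA	NA	NA
310	T	C	10.75	8.91	8.60	8.80	9.13	9.02	NA	3.55	NA
328	A	G	11.60	19.38	8.04	NA	NA	NA	NA	NA	NA
567	A	C	3.36	NA	NA	NA	NA	NA	NA	NA	NA
813	A	G	NA	NA	NA	NA	NA	NA	7.56	NA	NA
825	T	A	NA	NA	NA	NA	NA	NA	7.50	NA	NA
868	C	T	1.44	NA	NA	NA	NA	NA	NA	NA	NA
1039	A	G	NA	NA	NA	NA	NA	NA	1.19	NA	NA
1040	T	C	NA	NA	NA	NA	NA	NA	1.14	NA	NA
1106	C	T	NA	NA	NA	1.72	NA	NA	4.16	NA	NA
1120	C	T	1.67	NA	NA	3.23	NA	1.24	8.92	1.40	NA
1123	C	G	NA	NA	NA	NA	NA	NA	3.66	NA	NA
1556	C	T	2.14	NA	NA	3.68	NA	1.38	10.52	1.69	NA
1267	T	C	NA	NA	NA	2.09	NA	NA	6.55	NA	NA
1284	T	C	1.90	NA	NA	2.73	NA	1.16	8.20	NA	NA
1291	T	C	NA	NA	NA	1.98	NA	NA	6.49	NA	NA
1292	A	G	1.81	NA	NA	2.69	NA	NA	8.03	NA	NA
1520	T	C	NA	NA	NA	1.88	NA	NA	5.40	NA	NA
1536	A	G	NA	NA	NA	1.33	NA	NA	2.96	NA	NA
1619	C	T	1.46	NA	NA	1.81	NA	NA	5.07	NA	NA
1661	A	G	NA	NA	NA	50.55	1.41	NA	NA	NA	NA
1842	A	G	1.64	NA	NA	NA	NA	NA	3.11	NA	NA
1883	G	A	NA	NA	NA	NA	NA	NA	3.08	NA	NA
1888	G	A	NA	NA	NA	2.07	NA	NA	6.15	NA	NA
1889	C	A	NA	NA	NA	NA	NA	NA	2.24	NA	NA
1900	A	G	NA	NA	NA	NA	NA	NA	2.35	NA	NA
1944	C	T	NA	NA	NA	NA	NA	NA	2.07	NA	NA
1977	T	C	NA	NA	NA	1.63	NA	NA	4.56	NA	NA
1978	A	G	NA	NA	NA	NA	NA	NA	3.12	NA	NA
2000	C	T	NA	NA	NA	1.44	NA	NA	4.87	NA	NA
2056	G	A	NA	NA	NA	1.56	NA	NA	4.99	NA	NA
2059	C	T	NA	NA	NA	1.46	NA	NA	4.92	NA	NA
2080	T	C	NA	NA	NA	NA	NA	NA	2.04	NA	NA
2143	G	A	1.64	NA	NA	2.35	NA	NA	6.27	NA	NA
2162	C	T	1.65	NA	NA	2.30	NA	NA	6.30	NA	NA
2168	T	C	NA	NA	NA	NA	NA	NA	1.95	NA	NA
2523	C	T	1.74	1.29	1.35	2.84	NA	1.22	6.82	NA	NA
2541	C	A	NA	NA	NA	2.18	NA	NA	6.61	NA	NA
2557	C	T	NA	NA	NA	1.39	NA	NA	3.39	NA	NA
2572	C	T	NA	NA	NA	1.09	NA	NA	3.21	NA	NA
4048	G	A	NA	NA	NA	2.18	NA	NA	9.17	1.33	NA
4104	A	G	1.37	NA	NA	2.28	NA	NA	9.44	1.44	NA
4312	C	T	NA	NA	NA	2.10	NA	NA	10.29	NA	NA
4318	C	T	NA	NA	NA	2.10	NA	NA	10.29	NA	NA
4456	C	T	NA	NA	NA	2.11	NA	NA	12.22	1.84	NA
4736	T	C	NA	NA	NA	2.22	NA	NA	NA	NA	NA
4856	T	C	NA	NA	NA	1.87	NA	NA	8.50	NA	NA
4904	C	T	NA	NA	NA	NA	NA	NA	6.55	NA	NA
4914	C	T	NA	NA	NA	NA	NA	NA	6.54	NA	NA
4940	C	T	NA	NA	NA	1.31	NA	NA	6.04	NA	NA
4958	A	G	NA	NA	NA	NA	NA	NA	5.17	NA	NA
4991	G	A	NA	NA	NA	NA	NA	NA	5.08	NA	NA
5041	T	C	NA	NA	NA	1.74	NA	NA	5.39	NA	NA
5147	G	A	NA	NA	NA	1.72	NA	NA	7.60	NA	NA
5320	C	T	NA	NA	NA	2.13	NA	NA	9.85	1.19	NA
5351	A	G	NA	NA	NA	2.02	NA	NA	7.48	NA	NA
5385	C	T	NA	NA	NA	NA	NA	NA	2.11	NA	NA
5387	C	T	NA	NA	NA	1.97	NA	NA	7.39	NA	NA
5426	T	C	NA	NA	NA	2.01	NA	NA	NA	NA	NA
5471	G	A	NA	NA	NA	2.50	NA	NA	11.74	1.47	NA
5474	A	G	NA	NA	NA	2.45	NA	NA	11.67	1.43	NA
5493	T	C	NA	NA	NA	11.87	NA	NA	NA	NA	NA
5498	A	G	NA	NA	NA	2.49	NA	NA	11.73	1.40	NA
5580	T	C	NA	NA	NA	2.52	NA	NA	10.66	NA	NA
5821	G	A	NA	NA	NA	3.38	NA	NA	11.76	1.91	NA
5840	C	T	1.34	NA	NA	2.49	NA	NA	10.62	1.32	NA
6023	G	A	1.16	NA	NA	2.23	NA	NA	10.22	1.22	NA
6221	T	C	NA	NA	NA	2.02	NA	NA	8.99	NA	NA
6242	C	T	NA	NA	NA	1.60	NA	NA	7.39	NA	NA
6266	A	C	NA	NA	NA	1.47	NA	NA	7.32	NA	NA
6299	A	G	NA	NA	NA	1.74	NA	NA	8.30	NA	NA
6366	G	A	1.51	NA	NA	1.75	NA	NA	9.00	NA	NA
6383	G	A	NA	NA	NA	1.64	NA	NA	7.80	NA	NA
6405	A	G	NA	NA	NA	3.37	NA	NA	NA	NA	NA
6410	C	T	NA	NA	NA	1.45	NA	NA	6.34	NA	NA
6452	C	T	NA	NA	NA	1.45	NA	NA	6.30	NA	NA
6483	C	T	NA	NA	NA	1.50	NA	NA	6.49	NA	NA
6512	T	C	NA	NA	NA	1.77	NA	NA	7.14	NA	NA
6542	C	T	NA	NA	NA	1.61	NA	NA	7.00	NA	NA
6569	C	A	NA	NA	NA	1.99	NA	NA	9.19	NA	NA
6641	T	C	NA	NA	NA	2.26	NA	NA	10.11	1.18	NA
6935	C	T	NA	NA	NA	2.03	NA	NA	9.72	NA	NA
6938	C	T	NA	NA	NA	2.01	NA	NA	9.65	NA	NA
7146	A	G	1.40	NA	NA	2.71	NA	NA	11.46	1.37	NA
7195	T	C	NA	NA	NA	NA	NA	NA	3.26	NA	NA
7197	G	A	NA	NA	NA	2.53	NA	NA	NA	NA	NA
7216	G	A	NA	NA	NA	NA	NA	NA	3.42	NA	NA
7232	C	T	NA	NA	NA	2.09	NA	NA	8.77	NA	NA
7256	C	T	NA	NA	1.26	3.78	NA	1.40	13.51	1.70	NA
7286	T	C	NA	NA	NA	2.48	NA	NA	6.77	NA	NA
7299	A	G	NA	NA	NA	NA	NA	NA	4.98	NA	NA
7316	G	A	NA	NA	NA	1.53	NA	NA	6.96	NA	NA
7325	A	G	NA	NA	NA	NA	NA	NA	5.00	NA	NA
7337	G	A	NA	NA	NA	2.38	NA	NA	6.70	NA	NA
7364	A	G	NA	NA	NA	NA	NA	NA	5.14	NA	NA
7473	A	G	NA	NA	NA	NA	NA	NA	4.44	NA	NA
7521	G	A	NA	NA	NA	2.08	NA	NA	13.21	1.56	NA
7559	A	G	NA	NA	NA	NA	NA	NA	3.59	NA	NA
7571	A	G	NA	NA	NA	1.53	NA	NA	NA	NA	NA
7610	C	T	NA	NA	NA	NA	NA	NA	3.03	NA	NA
7650	C	T	NA	NA	NA	1.92	NA	NA	12.74	1.39	NA
7702	G	A	1.55	NA	NA	NA	NA	NA	NA	NA	NA
7705	T	C	NA	NA	NA	2.15	NA	NA	13.30	1.58	NA
7757	G	A	NA	NA	NA	2.07	NA	NA	3.46	NA	NA
7810	C	T	NA	NA	NA	1.75	NA	NA	11.54	NA	NA
7861	T	C	NA	NA	NA	NA	NA	NA	1.81	NA	NA
7868	C	T	NA	NA	NA	1.67	NA	NA	9.46	NA	NA
7891	C	T	NA	NA	NA	1.69	NA	NA	7.56	NA	NA
7912	G	A	NA	NA	NA	1.70	NA	NA	7.65	NA	NA
8021	A	G	1.28	NA	NA	2.13	NA	NA	7.48	NA	NA
8065	G	A	1.19	NA	NA	2.29	NA	NA	9.77	NA	NA
8167	T	C	NA	NA	NA	NA	NA	NA	3.98	NA	NA
8203	C	T	NA	NA	NA	2.06	NA	NA	9.85	NA	NA
8392	G	A	NA	NA	NA	1.73	NA	NA	11.20	NA	NA
8455	C	T	NA	NA	NA	1.64	NA	NA	10.07	NA	NA
8461	C	T	NA	NA	NA	1.64	NA	NA	10.02	NA	NA
8503	T	C	NA	NA	NA	1.72	NA	NA	9.10	NA	NA
8537	A	G	NA	NA	NA	6.70	NA	NA	NA	NA	NA
8545	G	A	NA	NA	NA	2.02	NA	NA	9.94	NA	NA
8655	C	T	NA	NA	NA	1.88	NA	NA	8.54	NA	NA
8677	A	C	NA	NA	NA	1.52	NA	NA	7.01	NA	NA
8701	A	G	1.52	NA	NA	1.70	NA	NA	7.13	NA	NA
8718	A	G	1.32	NA	NA	1.82	NA	NA	7.19	NA	NA
8943	C	T	NA	NA	NA	2.04	NA	NA	10.20	NA	NA
9060	C	A	NA	NA	NA	2.16	NA	NA	10.07	NA	NA
9075	C	T	1.41	NA	NA	2.29	NA	NA	10.68	1.30	NA
9168	C	T	1.45	NA	NA	2.25	NA	NA	10.33	1.26	NA
9254	A	G	1.33	NA	NA	2.44	NA	NA	9.71	1.28	NA
9325	T	C	NA	NA	NA	2.30	NA	NA	10.71	NA	NA
9329	G	C	NA	NA	NA	2.17	NA	NA	10.72	NA	NA
9434	A	G	NA	NA	NA	2.19	NA	NA	10.34	1.31	NA
9629	A	G	2.41	NA	NA	2.13	NA	NA	9.55	1.39	NA
10945	A	G	1.58	NA	NA	NA	NA	NA	1.52	NA	NA
10978	A	G	NA	NA	NA	NA	NA	NA	1.46	NA	NA
11016	G	A	NA	NA	NA	NA	NA	NA	1.45	NA	NA
11083	A	G	NA	NA	NA	1.98	NA	NA	6.30	NA	NA
11097	C	T	NA	NA	NA	1.94	NA	NA	6.29	NA	NA
11147	T	C	NA	NA	NA	1.79	NA	NA	4.82	NA	NA
11176	G	A	NA	NA	NA	1.43	NA	NA	3.16	NA	NA
11197	C	T	NA	NA	NA	1.40	NA	NA	3.16	NA	NA
11233	T	C	NA	NA	NA	NA	NA	NA	1.65	NA	NA
11527	C	T	NA	NA	NA	2.06	NA	NA	6.65	NA	NA
11557	A	G	NA	NA	NA	2.15	NA	NA	6.67	NA	NA
11590	A	G	NA	NA	NA	2.02	NA	NA	6.73	NA	NA
11662	T	C	NA	NA	NA	2.07	NA	NA	6.85	NA	NA
11852	G	A	NA	NA	NA	NA	NA	NA	3.14	NA	NA
11857	C	T	NA	NA	NA	NA	NA	NA	3.00	NA	NA
11887	G	A	NA	NA	NA	1.76	NA	NA	5.42	NA	NA
11914	G	A	1.89	1.43	1.47	1.80	NA	NA	5.43	NA	NA
11963	G	A	NA	NA	NA	1.65	NA	NA	5.75	NA	NA
12007	G	A	NA	NA	NA	1.67	NA	NA	5.85	NA	NA
12013	A	G	NA	NA	NA	1.76	NA	NA	5.87	NA	NA
12018	C	G	NA	NA	NA	NA	NA	NA	3.75	NA	NA
12561	G	A	NA	NA	NA	NA	NA	NA	3.71	NA	NA
12684	G	A	NA	NA	NA	2.26	NA	NA	10.52	1.60	NA
12705	C	T	NA	NA	NA	2.26	NA	NA	10.51	1.63	NA
13062	A	G	NA	NA	NA	2.21	NA	NA	10.83	1.59	NA
13095	T	C	1.96	NA	NA	2.38	NA	NA	9.43	1.64	NA
13105	A	G	1.80	NA	NA	2.32	NA	NA	9.41	1.55	NA
13242	A	G	NA	NA	NA	1.51	NA	NA	2.29	NA	NA
13260	T	C	NA	NA	NA	1.59	NA	NA	2.36	NA	NA
13272	C	T	NA	NA	NA	1.30	NA	NA	2.00	NA	NA
13281	T	C	NA	NA	NA	1.36	NA	NA	2.08	NA	NA
13359	G	A	NA	NA	NA	NA	NA	NA	3.54	NA	NA
13368	G	A	NA	NA	NA	NA	NA	NA	3.51	NA	NA
13386	T	C	1.28	NA	NA	1.78	NA	NA	5.13	NA	NA
13440	C	T	NA	NA	NA	1.61	NA	NA	4.89	NA	NA
13466	G	A	NA	NA	NA	1.55	NA	NA	4.70	NA	NA
13476	A	G	NA	NA	NA	1.55	NA	NA	4.65	NA	NA
13488	T	C	NA	NA	NA	1.76	NA	NA	4.99	NA	NA
13563	A	G	NA	NA	NA	NA	NA	NA	6.73	NA	NA
13581	T	C	NA	NA	NA	NA	NA	NA	6.73	NA	NA
14149	C	T	NA	NA	NA	NA	NA	NA	3.11	NA	NA
14170	A	T	NA	NA	NA	NA	NA	NA	3.15	NA	NA
14172	T	G	NA	NA	NA	1.58	NA	NA	4.74	NA	NA
14182	T	C	NA	NA	NA	1.74	NA	NA	4.90	NA	NA
14950	C	T	NA	NA	NA	NA	NA	NA	3.74	NA	NA
14956	T	C	NA	NA	NA	1.21	NA	NA	3.85	NA	NA
14969	T	C	NA	NA	NA	NA	NA	NA	3.72	NA	NA
15191	T	C	1.84	1.50	1.69	NA	NA	NA	NA	NA	NA
15301	G	A	2.80	1.92	2.19	NA	NA	NA	NA	NA	NA
16129	G	A	NA	NA	NA	9.25	NA	NA	NA	NA	NA
16182	A	C	NA	NA	NA	NA	NA	NA	26.73	24.66	23.82
16183	A	C	NA	NA	NA	NA	NA	NA	60.43	58.92	60.06
16444	C	T	NA	NA	NA	1.42	NA	NA	NA	NA	NA
16496	G	A	NA	NA	NA	1.50	NA	NA	NA	NA	NA
16527	C	T	NA	NA	NA	2.08	NA	NA	NA	NA	NA
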