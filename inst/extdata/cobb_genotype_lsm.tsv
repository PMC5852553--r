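snp	chrom	pos	n	genotype	lsm	sd	letters	additive_reported	dominance_reported
rs15213482	chr1	25118696	125	AA	35.02	7.65	B	14.41	-10.70
rs15213482	chr1	25118696	330	AG	9.91	4.69	A	14.41	-10.70
rs15213482	chr1	25118696	320	GG	6.20	4.76	A	14.41	-10.70
rs318069175	chr1	25124828	318	AA	6.08	4.79	A	-12.95	-8.31
rs318069175	chr1	25124828	329	AG	10.72	4.71	A	-12.95	-8.31
rs318069175	chr1	25124828	127	GG	31.98	7.63	B	-12.95	-8.31
chr2_145118378	chr2	145118378	276	CC	1.57	5.14	A	-12.65	0.17
chr2_145118378	chr2	145118378	357	TC	14.39	4.50	AB	-12.65	0.17
chr2_145118378	chr2	145118378	141	TT	26.86	7.18	B	-12.65	0.17
rs315791208	chr2	23470408	166	AA	-3.58	6.62	A	-8.82	12.43
rs315791208	chr2	23470408	380	AG	17.67	4.36	B	-8.82	12.43
rs315791208	chr2	23470408	230	GG	14.05	5.61	B	-8.82	12.43
rs313915675	chr2	39376196	623	AA	9.67	3.44	a	10.14	29.01
rs313915675	chr2	39376196	123	AC	28.55	7.72	b	10.14	29.01
rs313915675	chr2	39376196	27	CC	-10.60	16.47	a	10.14	29.01
rs315951802	chr2	56946139	64	AA	-1.63	10.68	a	-10.64	-3.53
rs315951802	chr2	56946139	293	AG	5.49	5.00	a	-10.64	-3.53
rs315951802	chr2	56946139	417	GG	19.66	4.2	b	-10.64	-3.53
rs318158632	chr4	5122558	249	AA	14.44	5.41	b	8.36	11.93
rs318158632	chr4	5122558	362	AG	18.01	4.50	b	8.36	11.93
rs318158632	chr4	5122558	167	GG	-2.29	6.59	a	8.36	11.93
rs315081661	chr4	12239357	215	CC	15.95	5.82	b	8.83	10.09
rs315081661	chr4	12239357	386	TC	17.21	4.35	b	8.83	10.09
rs315081661	chr4	12239357	175	TT	-1.71	6.45	a	8.83	10.09
chr5_16429960	chr5	16429960	246	AA	23.49	5.46	b	10.08	-5.28
chr5_16429960	chr5	16429960	363	AT	8.13	4.50	a	10.08	-5.28
chr5_16429960	chr5	16429960	164	TT	3.33	6.70	a	10.08	-5.28
rs316109660	chr10	1504159	50	AA	32.29	12.03	b	7.97	-20.56
rs316109660	chr10	1504159	325	AG	3.76	4.72	a	7.97	-20.56
rs316109660	chr10	1504159	400	GG	16.34	4.27	b	7.97	-20.56
chr18_4638932	chr18	4638932	223	CC	23.67	5.72	B	10.90	-1.90
chr18_4638932	chr18	4638932	361	CG	10.86	4.48	AB	10.90	-1.90
chr18_4638932	chr18	4638932	193	GG	1.86	6.16	A	10.90	-1.90
chrZ_46332884	chrZ	46332884	133	AA	12.64	7.68	AB	-2.78	-20.25
chrZ_46332884	chrZ	46332884	145	AG	-4.82	7.53	A	-2.78	-20.25
chrZ_46332884	chrZ	46332884	497	GG	18.21	3.90	B	-2.78	-20.25
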