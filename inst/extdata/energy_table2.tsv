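id	parent	symbol1	symbol2	geometry	e_int_modified	e_int_unmodified	e_mod
1	A	m1A	A	tHW	-19.74	-12.24	-7.50
2	A	m1A	U	tHW(w)	-31.13	-20.11	-11.02
3	A	m1A	U	tHW	-21.75	-15.72	-6.03
4	A	m1A	m5U	tHW	-22.54	-15.79	-6.35
5	A	m66A	G	tS(w)S(r)	-18.46	-17.24	-1.22
6	G	m1G	C	tHH1	-10.67	-10.38	-0.29
7	G	m2G	U	cWW	-15.77	-15.59	-0.18
8	G	m2G	C	cWW	-27.90	-27.02	-0.88
9	G	m2G	C	cWW1	-17.60	-27.02	9.42
10	G	m22G	A	cWW	-16.09	-17.19	1.10
11	G	m7G	C	cWW	-37.17	-27.02	-10.15
12	G	m7G	G	tWH	-34.55	-19.43	-15.12
13	C	m5C	G	cWW	-27.68	-27.02	-0.66
14	C	m5C	G	tWW	-17.96	-17.49	-0.47
4	U	m5U	m1A	tWH	-22.54	-21.74	-0.80
15	U	m5U	A	tWH	-15.80	-15.72	-0.08
16	U	m5U	G	cWW	-16.00	-15.59	-0.41
17	U	m5U	G	tWH1	-9.83	-10.08	0.25
18	U	s4U	A	tWH	-16.11	-15.72	-0.39
19	U	H2U	U	tWW	-11.86	-11.84	-0.02
20	U	H2U	G	cHS1	-8.55	-8.29	-0.26
21	U	H2U	G	tWS	-13.72	-13.66	-0.06
22	U	Psi	A	cWW	-14.54	-14.93	0.39
23	U	Psi	A	cHW	-16.00	-9.09	-6.91
24	U	Psi	U	tWW	-12.35	-12.77	0.42
25	U	Psi	G	tBsW	-12.85	-13.23	0.38
26	U	Psi	G	cWW	-16.82	-15.59	-1.23
27	U	Psi	C	cS(r)W	-19.44	-21.03	1.59
1n	N	5BrC	G	cWW	-26.59	-27.02	0.43
2n	N	5BrU	A	cWW	-15.35	-14.93	-0.42
3n	N	5BrU	G	cWW	-15.96	-15.59	-0.37
4n	N	5BrU	5BrU	cWW	-12.63	-12.19	-0.44
5n	N	5BrU	A	cWH	-16.41	-15.98	-0.43
6n	N	5BrU	A	cS(r)H	-17.31	-17.27	-0.04
7n	N	5BrU	A	cW(r)S	-17.89	-17.93	0.04
8n	N	5IU	A	cWW	-15.35	-14.93	-0.42
9n	N	5IU	G	cWW	-15.91	-15.59	-0.32
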