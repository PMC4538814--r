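id	symbol1	symbol2	geometry	occurrences	position	chains	pdb_id	resolution	rna	source	natural
1	m1A	A	tHW	1	58:54	A	1YFG	3.00	tRNA(iMet)	S.cerevisiae	1
2	m1A	U	tHW(w)	44	628:624	0	1VQ5	2.60	23S_rRNA	H.marismortui	1
3	m1A	U	tHW	1	58:54	B	1OB2	3.35	tRNA(Phe)	E.coli	1
4	m1A	m5U	tHW	19	58:54	A	1EHZ	1.93	tRNA(Phe)	S.cerevisiae	1
5	m66A	G	tS(w)S(r)	1	76:2618	4:0	1VQ6	2.70	23S_rRNA	H.marismortui	1
6	m1G	C	tHH1	1	9:23	A	1YFG	3.00	tRNA(iMet)	S.cerevisiae	1
7	m2G	U	cWW	1	6:67	A	1FIR	3.30	tRNA(Lys3)	B.taurus	1
8	m2G	C	cWW	23	10:25	A	1EHZ	1.93	tRNA(Phe)	S.cerevisiae	1
9	m2G	C	cWW1	3	10:25	B	1OB5	3.10	tRNA(Phe)	E.coli	1
10	m22G	A	cWW	20	26:44	A	1EHZ	1.93	tRNA(Phe)	S.cerevisiae	1
11	m7G	C	cWW	7	527:522	A	4DR2	3.25	16S_rRNA	T.thermophilus	1
12	m7G	G	tWH	27	46:22	A	1EHZ	1.93	tRNA(Phe)	S.cerevisiae	1
13	m5C	G	cWW	57	40:30	A	1EHZ	1.93	tRNA(Phe)	S.cerevisiae	1
14	m5C	G	tWW	3	548:515	Y	2DLC	2.40	tRNA(Tyr)	S.cerevisiae	1
15	m5U	A	tWH	38	654:658	B	1C0A	2.40	tRNA(Asp)	E.coli	1
16	m5U	G	tWH1	2	54:58	T	1H4S	2.85	tRNA(Pro)	T.thermophilus	1
17	m5U	G	cWW	2	1:10	D:B	1U6B	3.10	ribozyme	Azoarcus	1
18	s4U	A	tWH	21	608:614	B	1C0A	2.40	tRNA(Asp)	E.coli	1
19	H2U	U	tWW	12	916:959	C	1IL2	2.60	tRNA(Asp)	S.cerevisiae	1
20	H2U	G	cHS1	1	620:619	B	1C0A	2.40	tRNA(Asp)	E.coli	1
21	H2U	G	tWS	1	20A:15	T	1SER	2.90	tRNA(Ser)	T.thermophilus	1
22	Psi	A	cWW	24	6:21	A:B	3CGP	1.57	U2_snRNA	mammalian	1
23	Psi	A	cHW	1	39:31	D	1TTT	2.70	tRNA(Phe)	S.cerevisiae	1
24	Psi	U	tWW	45	2621:1838	0	4HUB	2.40	23S_rRNA	H.marismortui	1
25	Psi	G	tBsW	48	955:917	C	1IL2	2.60	tRNA(Asp)	S.cerevisiae	1
26	Psi	G	cWW	14	6:20	A:B	3CGS	1.65	U2_snRNA	mammalian	1
27	Psi	C	cS(r)W	7	516:519	A	4DR2	3.25	16S_rRNA	T.thermophilus	1
1n	5BrC	G	cWW	16	3:29	A:B	1QBP	2.10	synthetic	NA	0
2n	5BrU	A	cWW	95	2:22	A	1ZCI	1.65	viral_genome	HIV-1	0
3n	5BrU	G	cWW	16	142:155	B	1JID	1.80	SRP_RNA	H.sapiens	0
4n	5BrU	5BrU	cWW	2	5:21	C	1RLG	2.70	snoRNA	A.fulgidus	0
5n	5BrU	A	cWH	1	38:7	A	1KH6	2.90	viral_genome	HCV	0
6n	5BrU	A	cS(r)H	1	37:6	A	1KH6	2.90	viral_genome	HCV	0
7n	5BrU	A	cW(r)S	1	11:26	A	1F1T	2.80	RNA_aptamer	NA	0
8n	5IU	A	cWW	13	13:2	D:C	464D	1.23	synthetic	NA	0
9n	5IU	G	cWW	4	6:4	C:D	1YVP	2.20	synthetic	NA	0
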