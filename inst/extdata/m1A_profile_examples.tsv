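ref_seg	mod	pos	ref_base	cov	pre_base	mism_rate	A	G	T	C	N	a	g	t	c	n	single_jump_rate_direct	single_jump_rate_delayed	double_jump_rate	arrest_rate
tdbR00000369|Saccharomyces_cerevisiae|4932|Arg|ACG	m1A	58	A	167	G	0.94012	10	39	24	7	0	0	58	25	4	0	0.00000	0.01754	0.01754	0.23661
tdbR00000370|Saccharomyces_cerevisiae|4932|Arg|TCT	m1A	57	A	25	C	0.52000	12	0	0	6	1	0	0	0	6	0	0.00000	0.00000	0.00000	0.03846
tdbR00000300|Saccharomyces_cerevisiae|4932|Asn|GTT	m1A	59	A	553	C	0.93671	35	4	7	229	1	0	5	11	261	0	0.00318	0.08493	0.40552	0.09519
tdbR00000021|Saccharomyces_cerevisiae|4932|Cys|GCA	m1A	57	A	562	T	0.94128	33	12	205	17	2	0	18	266	9	0	0.00000	0.00000	0.00858	0.09048
tdbR00000170|Saccharomyces_cerevisiae|4932|Ile|AAT	m1A	59	A	1177	T	0.96517	41	15	447	74	4	0	16	540	40	0	0.00168	0.00168	0.00587	0.23181
tdbM00000006|Saccharomyces_cerevisiae|4932|Ile|TAT	m1A	58	A	447	T	0.85682	64	15	138	23	1	0	25	161	20	0	0.00000	0.00665	0.00000	0.46437
tdbR00000251|Saccharomyces_cerevisiae|4932|Leu|TAA	m1A	69	A	571	A	0.35902	366	16	58	57	1	0	13	37	23	0	0.00520	0.00000	0.00173	0.43098
tdbR00000250|Saccharomyces_cerevisiae|4932|Leu|TAG	m1A	67	A	544	A	0.55699	241	17	96	41	2	0	22	87	38	0	0.01961	0.00000	0.00713	0.26988
tdbR00000192|Saccharomyces_cerevisiae|4932|Lys|CTT	m1A	58	A	604	G	0.72682	165	90	85	12	2	0	127	114	9	0	0.03343	0.00304	0.04407	0.17955
tdbR00000193|Saccharomyces_cerevisiae|4932|Lys|TTT	m1A	58	A	257	G	0.86381	35	36	53	9	1	0	46	69	8	0	0.07190	0.00000	0.06863	0.19895
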