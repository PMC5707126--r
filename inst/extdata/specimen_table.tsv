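group	specimen	pmi	age	sex	collection_year	clinical_history	hq_reads_millions
control	202	4	57	M	1983	Post-surgical infection	91.5
control	214	4	56	M	1981	Heart Disease	94.7
control	3276	19	54	M	2002	Heart Disease	93.9
control	33	5	69	M	1983	Lung Disease	89.1
control	3371	16	52	M	2002	Lung Cancer	96.8
control	3406	20	72	F	2002	Heart Failure	89.3
control	3465	20	93	F	2002	Bleeding	105.2
control	3482	14	79	F	2003	Heart Disease	97.5
control	3543	12	73	F	2003	Lung Disease	105.2
control	3348	9	76	F	2002	Heart Disease, Diabetes	102.7
control	3465b	11	76	M	2003	Heart Failure	107.3
control	3637	13	76	M	2003	Pneumonia	102.5
control	3641	20	76	M	2003	Stomach and Liver Cancer	85.3
control	3698	17	84	F	2003	Breast Cancer	90.3
demyelination	168	3	37	F	1984	PPMS	89.7
demyelination	2443	26	49	F	1997	PPMS	99
demyelination	2485	9	69	M	1997	PPMS	63.3
demyelination	2696	21	86	F	1998	PPMS	130.9
demyelination	2946	15	59	M	1999	PPMS	88.9
demyelination	3161	20	51	F	2001	Secondary Progressive MS	89.9
demyelination	3185	14	50	M	2001	PPMS	91.1
demyelination	3509	11	74	F	2003	PPMS	87.2
demyelination	3816	21	47	F	2004	PPMS	91
demyelination	3840	23	61	F	2003	PPMS	95
demyelination	3931	10	74	F	2004	PPMS	73.8
demyelination	5149	8	48	M	2010	PPMS	66.4
demyelination	108	2	56	F	1998	NMO	72.5
demyelination	290	NA	NA	NA	NA	NMO	82.3
OND	1418	5	68	M	1988	MS-like illness	76.8
OND	4403	18	77	F	2006	HSV encephalitis, stroke	99.5
OND	4471	12	73	F	2007	Rasmussen's encephalitis	49.4
OND	710	8	58	M	1983	HSV encephalitis, chronic lymphocytic leukemia	50.1
OND	924	24	86	M	1985	HSV encephalitis	67.9
OND	coloradoA	NA	NA	NA	NA	SSPE (measles)	67.9
OND	coloradoB	NA	NA	NA	NA	SSPE (measles)	66.9
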