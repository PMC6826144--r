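rsid	chrom	pos	effect_allele	other_allele	eaf	beta_sd	se_sd	locus
rs10936599	3	169774313	C	T	0.75	0.1087	0.014	TERC
rs2736100	5	1286516	C	A	0.51	0.079	0.011	TERT
rs7675998	4	163086668	A	G	0.78	0.0836	0.012	NAF1
rs9420907	10	103916188	C	A	0.87	0.0957	0.015	OBFC1
rs8105767	19	22032639	G	T	0.7	0.0604	0.01	ZNF208
rs755017	20	63790269	G	A	0.87	0.0836	0.014	RTEL1
rs11125529	2	54248729	A	C	0.14	0.0604	0.012	ACYP2
rs6772228	3	58376019	A	T	0.94	0.0818	0.017	PXK
rs9257445	6	28554603	G	T	0.58	0.0418	0.009	ZNF311
rs6028466	20	39500359	A	T	0.86	0.0539	0.012	DHX35
rs2967374	16	74640950	G	A	0.79	0.0465	0.01	MPHOSPH6
rs3027234	17	8271089	C	T	0.77	0.0511	0.011	CTC1
rs4691895	4	163108608	C	G	0.78	0.0557	0.012	NAF1
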