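rsid	chrom	pos	effect_allele	other_allele	eaf	or	se	pvalue	proxy_of
rs11420276	1	44184192	G	GT	0.696	1.11305	0.0149	6.452e-13	.
rs11591402	10	106747354	A	T	0.224	0.91174	0.0164	1.76e-08	.
rs1222067	1	96597502	A	C	0.688	0.92635	0.0155	7.908e-07	rs1222063
rs1427829	2	89760744	A	G	0.434	1.08567	0.0136	1.349e-09	.
rs12596294	16	72587093	A	T	0.098	1.12008	0.0207	4.157e-08	rs212178
rs281324	15	47754018	T	C	0.531	0.92450	0.0135	6.684e-09	.
rs7674790	4	31149277	A	T	0.610	1.07455	0.014	2.996e-07	rs28411770
rs17808771	3	20691823	A	T	0.758	1.07326	0.0153	3.773e-06	rs4858241
rs4916723	5	87854395	A	C	0.573	0.92515	0.0138	1.807e-08	.
rs5886709	7	114086133	G	GTC	0.463	1.07993	0.0137	2.056e-08	.
rs6990255	8	34126948	T	C	0.0586481	1.18270	0.0315	1.03e-07	rs74760947
rs9677504	2	215181889	A	G	0.109	1.12019	0.0213	9.829e-08	.
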