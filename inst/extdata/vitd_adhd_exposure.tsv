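rsid	gene	effect_allele	other_allele	eaf	beta	se	pvalue	proxy_of
rs10741657	CYP2R1	A	G	0.40	0.031	0.0022	2.05e-46	.
rs10745742	AMDHD1	T	C	0.40	0.017	0.0022	1.88e-14	.
rs12785878	NADSYN1-DHCR7	T	G	0.75	0.036	0.0022	3.80e-62	.
rs209955	CYP24A1	T	C	0.31	-0.019	0.0024	2.49e-16	rs17216707
rs3755967	GC	T	C	0.28	-0.089	0.0023	4.74e-343	.
rs8018720	SEC23A	C	G	0.82	-0.017	0.0029	4.72e-09	.
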