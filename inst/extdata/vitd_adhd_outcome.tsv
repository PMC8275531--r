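rsid	effect_allele	other_allele	or	se	pvalue
rs10741657	A	G	1.0048	0.0137	0.728
rs10745742	T	C	1.0141	0.0138	0.311
rs12785878	T	G	1.0313	0.0146	0.035
rs209955	T	C	1.003	0.0156	0.848
rs3755967	T	C	1.0235	0.015	0.122
rs8018720	C	G	0.9958	0.0185	0.819
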