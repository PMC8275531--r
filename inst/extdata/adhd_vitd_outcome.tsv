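rsid	effect_allele	other_allele	beta	se	pvalue
rs11591402	A	T	0.0012	0.0025	0.6195
rs1222067	A	C	0.0008	0.0026	0.7464
rs1427829	A	G	0.0027	0.0021	0.1974
rs12596294	A	T	0.0029	0.0034	0.3873
rs281324	T	C	0.0024	0.0021	0.2426
rs7674790	A	T	0.0002	0.0022	0.9348
rs17808771	A	T	0.0008	0.0024	0.7341
rs4916723	A	C	-0.0016	0.0021	0.4515
rs6990255	T	C	-0.0058	0.0043	0.1779
rs9677504	A	G	0.0012	0.0033	0.7171
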