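lead_rsid	proxy_rsid	r2	distance	a1	a2
rs17216707	rs209955	0.4115	-9491	T	C
rs1222063	rs1222067	0.679350	-4938	A	C
rs212178	rs12596294	0.924371	8962	A	T
rs28411770	rs7674790	0.797643	-2179	A	T
rs4858241	rs17808771	0.646552	22752	A	T
rs74760947	rs6990255	0.947204	-225662	T	C
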