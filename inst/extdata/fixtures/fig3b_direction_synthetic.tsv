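rsid	gene	cancer_effect_allele	cancer_other_allele	cancer_z	cancer_p	eqtl_effect_allele	eqtl_other_allele	eqtl_z	eqtl_p
rs2070721	IRF1	G	T	-5.5	3.8e-08	G	T	-30.0	1.2e-197
rs10230978	IKZF1	G	A	-5.2	2.0e-07	G	A	12.0	3.7e-33
rs3740688	SPI1	T	G	6.1	1.1e-09	T	G	25.0	5.0e-138
rs3184504	SH2B3	C	T	5.8	6.6e-09	C	T	-40.0	1.0e-300
rs4788115	LAT	A	G	-5.4	6.7e-08	A	G	-18.0	1.3e-72
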