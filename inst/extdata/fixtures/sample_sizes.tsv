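trait	abbrev	class	cases	controls
breast_cancer	BC	cancer	122977	105974
ovarian_cancer	OC	cancer	25509	40941
prostate_cancer	PC	cancer	79148	61106
endometrial_cancer	EC	cancer	12906	108979
crohns_disease	CD	autoimmune	4474	9500
ulcerative_colitis	UC	autoimmune	4173	9500
rheumatoid_arthritis	RA	autoimmune	29880	73758
systemic_lupus_erythematosus	SLE	autoimmune	7219	15991
hashimoto_thyroiditis	HT	autoimmune	30234	725172
multiple_sclerosis	MS	autoimmune	14498	24091
type_1_diabetes	T1D	autoimmune	22153	37374
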