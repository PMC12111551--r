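subtype	parent	cases	controls
er_positive_breast	breast_cancer	69501	105974
er_negative_breast	breast_cancer	21468	105974
high_grade_serous_ovarian	ovarian_cancer	13037	40941
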