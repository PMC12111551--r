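analysis	n_leads
breast	80
er_positive_breast	83
er_negative_breast	35
ovarian	27
high_grade_serous_ovarian	20
prostate	101
endometrial	52
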