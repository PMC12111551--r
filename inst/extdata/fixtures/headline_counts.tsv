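quantity	value
total_lead_snps	398
unique_lead_snps	312
single_pair_lead_snps	244
multi_pair_lead_snps	68
cancer_cases	240540
cancer_controls	317000
autoimmune_cases	112631
autoimmune_controls	895386
immune_related_genes	32
immport_genes	16
enrichr_genes	20
both_methods_genes	4
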