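snp_id	population	kind	hom_alt	het	hom_ref	alt	ref	frequency	n_alleles	assume_no_hom_alt
rs141193530	ExAC_NFE	genotype	6	519	32827	NA	NA	NA	NA	FALSE
rs141193530	1kGP_EUR	allele	NA	NA	NA	5	1001	NA	NA	TRUE
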