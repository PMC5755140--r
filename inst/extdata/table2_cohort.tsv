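snp_id	population	hom_alt	het	hom_ref
rs141193530	nmsc_cohort	0	7	202
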