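snp_id	gene	location	af_obs	af_eur	reported_test
rs55927162	GRHL3	intergenic	0.6667	0.21	chi2
rs56256719	GRHL3	intergenic	0.697	0.24	chi2
rs151171718	GRHL3	intronic	0.0455	0.0013	fisher
rs141193530	GRHL3	exon11_P455A	0.0758	0.004	chi2
rs151326764	GRHL3	exon16_R573H	0.0303	0.0026	fisher
rs548650	GRHL2	intronic	0.0909	0.02	chi2
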