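library	fully_called_genome_fraction	fully_called_exome_fraction	gross_mapping_gb	both_mates_gb	genome_cov5x_fraction	exome_cov5x_fraction	snv_total	snv_hom	snv_het	ena_accession
STD	0.972	0.988	343	306	0.997	0.999	3241932	1531723	1635402	ERS823996
LFR1	0.915	0.928	298	217	0.981	0.98	2856624	1382653	1195290	ERS823998
LFR2	0.9	0.92	261	171	0.978	0.98	2890506	1241444	1239735	ERS823997
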