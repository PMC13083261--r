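label	numerator	denominator	unit	digits
gcf_per_species_reef	6612	4224	ratio	2
gcf_per_species_ocean	5877	8304	ratio	2
gcf_per_species_coral	2781	971	ratio	1
gcf_per_species_sponge	3920	3206	ratio	1
gcf_per_genome_coral	2781	2046	ratio	1
gcf_per_genome_sponge	3920	11400	ratio	1
pct_fire_coral_mags	1171	2046	percent	0
pct_stony_coral_mags	793	2046	percent	0
pct_soft_coral_mags	72	2046	percent	0
pct_species_new_to_reference	3774	4224	percent	0
pct_tara_species_new	638	645	percent	0
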