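# SYNTHETIC example input for the genome-coverage estimator.
# Abundances are invented SSU-rRNA read proportions for a community shaped
# like a sulfur-spring deposit (they are NOT measurements); genome sizes
# are round values typical of the named genera. Blank genome_size_bp falls
# back to the 3 Mb default.
otu	abundance_proportion	genome_size_bp
Sulfurovum	0.55	2600000
Sulfuricurvum	0.25	3000000
Flavobacterium	0.12	3300000
Burkholderia	0.008	7200000
Ralstonia	0.001	5600000
other	0.071	
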