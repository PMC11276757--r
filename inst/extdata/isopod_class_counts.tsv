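species_id	snp_class	covered_nonsyn_sites	covered_syn_sites	nonsyn_snps	syn_snps
H_riparius	all_snps	881978	237763	657	2289
T_pusillus	candidate_novel	1593394	434906	12	17
T_pusillus	ancestral_identical	1593394	434906	338	1602
H_riparius	low_frequency	881978	237763	388	1209
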