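species_id	n_female	n_male
T_pusillus	170	0
H_riparius	7	4
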