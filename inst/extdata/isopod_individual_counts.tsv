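sample_id	species_id	role	covered_nonsyn_sites	covered_syn_sites	nonsyn_snps	syn_snps
T_rathkei_F	T_rathkei	adult	2530937	688108	1521	2820
T_rathkei_M	T_rathkei	adult	1738784	474958	976	2530
H_riparius_F1	H_riparius	adult	1724304	466443	832	2904
H_riparius_F2	H_riparius	adult	3484506	944256	1662	2546
H_riparius_M1	H_riparius	adult	1704014	461491	700	1860
H_riparius_M3	H_riparius	adult	1976952	537642	590	1576
T_pusillus_5	T_pusillus	adult	2548636	700295	4300	13816
T_pusillus_75	T_pusillus	adult	2719388	742972	4250	14107
T_pusillus_170	T_pusillus	adult	3316605	910803	6164	19884
T_pusillus_85	T_pusillus	adult	2358416	645793	4065	13592
T_pusillus_85_offspring	T_pusillus	offspring_pool	334041	90801	248	1290
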