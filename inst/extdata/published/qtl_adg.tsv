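window	population	start_snp	end_snp	n_snps	pct_genetic_variance	nominal_p	bonferroni_p	lead_snp	sppi
5_106	Hereford	rs135296291	rs137324049	312	3.13	1.37E-7	3.67E-4	rs132862617	0.09
6_38	CycleVII	rs29010895	rs81131471	21	1.43	1.27E-5	3.21E-2	rs109294917	0.36
7_93	Hereford	rs134145330	rs109802727	183	9.18	1.07E-10	2.87E-7	rs109618368	0.11
8_0	Hereford	rs133933459	rs134191169	287	2.60	4.21E-7	1.13E-3	rs136695610	0.07
20_8	CycleVII	rs110676036	rs41638185	25	2.42	6.45E-7	1.63E-3	rs42602138	0.60
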