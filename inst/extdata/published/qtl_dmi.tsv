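window	population	start_snp	end_snp	n_snps	pct_genetic_variance	nominal_p	bonferroni_p	lead_snp	sppi
1_107	Angus	rs137640861	rs133218870	210	1.64	1.52E-5	4.08E-2	rs136742116	0.10
3_70	Hereford	rs134410518	rs136347800	195	4.33	7.23E-8	1.94E-4	rs109239108	0.14
7_0	Angus	rs134214229	rs133987755	219	2.78	9.14E-7	2.45E-3	rs134458731	0.49
7_23	Angus	rs133100477	rs42926834	261	10.39	2.97E-10	7.97E-7	rs133232710	0.44
21_13	Angus	rs109890770	rs137407067	277	1.75	1.09E-5	2.92E-2	rs134953219	0.31
X_115	Hereford	rs109289869	rs133784615	214	1.95	6.20E-6	1.66E-2	rs134244037	0.16
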