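window	population	start_snp	end_snp	n_snps	pct_genetic_variance	nominal_p	bonferroni_p	lead_snp	sppi
1_98	Angus	rs41638981	rs110173036	265	1.94	1.07E-5	2.88E-2	rs135605472	0.55
6_38	CycleVII	rs29010895	rs81131471	21	3.49	4.78E-7	1.21E-3	rs109294917	0.55
6_39	CycleVII	rs81139192	rs81129153	25	2.08	7.52E-6	1.89E-2	rs110012183	0.54
7_0	Angus	rs134214229	rs133987755	219	3.99	2.26E-7	6.08E-4	rs134458731	0.89
7_23	Angus	rs133100477	rs42926834	261	14.24	8.99E-11	2.41E-7	rs136491020	0.57
7_93	Hereford	rs134145330	rs109802727	183	2.55	2.61E-6	7.00E-3	rs110680622	0.05
14_24	SimAngus	rs109637592	rs109636480	192	3.14	8.54E-7	2.29E-3	rs134751608	0.08
18_63	Hereford	rs110348373	rs42522614	225	1.76	1.75E-5	4.69E-2	rs41897307	0.39
20_4	Hereford	rs134565601	rs43094976	299	3.78	3.07E-7	8.23E-4	rs133032375	0.08
20_6	SimAngus	rs42517095	rs42352270	288	2.58	2.45E-6	6.56E-3	rs133488748	0.07
21_13	Angus	rs109890770	rs137407067	277	1.97	9.92E-6	2.66E-2	rs41592029	0.54
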