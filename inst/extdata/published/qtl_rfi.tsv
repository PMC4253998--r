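window	population	start_snp	end_snp	n_snps	pct_genetic_variance	nominal_p	bonferroni_p	lead_snp	sppi
6_50	Angus	rs133728493	rs136948693	304	2.21	1.10E-6	2.95E-3	rs137524648	0.04
10_85	SimAngus	rs110164488	rs43652141	230	1.58	7.37E-6	1.97E-2	rs136969055	0.06
14_41	SimAngus	rs42509065	rs133984439	201	1.75	4.17E-6	1.12E-2	rs136041102	0.31
14_43	CycleVII	rs109845775	rs110706635	12	1.95	2.26E-6	5.70E-3	rs41617069	0.70
15_82	SimAngus	rs110524424	rs42781637	380	2.40	6.78E-7	1.81E-3	rs41785720	0.05
18_22	Angus	rs41579995	rs132921208	292	1.60	6.88E-6	1.85E-2	rs109634056	0.07
18_37	SimAngus	rs110857287	rs43211307	241	1.35	1.74E-5	4.65E-2	rs137177006	0.03
19_54	Hereford	rs134654442	rs110630064	353	1.45	1.18E-5	3.17E-2	rs109988749	0.21
20_4	Hereford	rs134565601	rs43094976	299	1.57	7.64E-6	2.05E-2	rs133032375	0.05
25_7	SimAngus	rs110477162	rs110037478	289	1.45	1.18E-5	3.16E-2	rs137078861	0.04
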