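trait	population	h2	va	ve
ADG	CycleVII	0.30	0.01	0.03
ADG	Angus	0.19	0.01	0.05
ADG	Hereford	0.27	0.02	0.05
ADG	SimAngus	0.23	0.01	0.03
DMI	CycleVII	0.35	0.39	0.71
DMI	Angus	0.35	0.85	1.55
DMI	Hereford	0.41	0.66	0.94
DMI	SimAngus	0.27	0.28	0.75
MBW	CycleVII	0.47	25.73	29.49
MBW	Angus	0.49	38.08	39.78
MBW	Hereford	0.50	24.02	23.79
MBW	SimAngus	0.38	8.58	14.17
RFI	CycleVII	0.49	0.19	0.19
RFI	Angus	0.21	0.27	0.98
RFI	Hereford	0.45	0.32	0.40
RFI	SimAngus	0.32	0.20	0.42
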