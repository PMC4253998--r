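trait	n	mean	sd	neg2loglik	gamma	delta	theta	sigma
ADG	2684	0.039	0.017	-14665.593	-0.514	1.772	0.031	0.023
DMI	2684	0.042	0.048	-12985.369	-1.019	0.924	0.018	0.009
MBW	2684	0.043	0.054	-12578.502	-0.996	0.908	0.017	0.010
RFI	2684	0.041	0.045	-13090.396	-1.001	0.976	0.018	0.010
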