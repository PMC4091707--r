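tf	f0	gamma	beta	e_minus_mu	daic_cfd_ufd	daic_exp_ufd	w_ufd	w_cfd	w_exp
REB1	0.999	18.2	0.794	threshold	3.054	35.734	0.822	0.178	1.43e-8
ROX1	0.993	335	0.398	tail	-2.042	34.753	0.265	0.735	7.53e-9
MET32	0.973	133	0.251	tail	-2.233	10.540	0.246	0.752	0.001
RPN4	1.01e-4	1.58	2.0	threshold	5.674	19.959	0.945	0.055	4.38e-5
MET31	4.54e-5	1.58	1.58	threshold	-1.469	-3.869	0.100	0.208	0.692
PDR3	0.988	242	0.251	tail	-2.124	6.123	0.254	0.734	0.012
YAP7	4.54e-5	1.58	1.0	threshold	-2.049	10.722	0.264	0.735	0.001
BAS1	4.54e-5	2.51	0.501	threshold	-2.107	1.061	0.224	0.644	0.132
STB5	0.401	150	0.316	plateau	-2.732	-7.145	0.025	0.097	0.879
AFT1	4.54e-5	3.98	5.01	threshold	-2.069	6.096	0.259	0.729	0.012
CUP9	0.978	219	0.316	tail	-2.251	1.560	0.220	0.679	0.101
MCM1	0.998	83.1	0.251	tail	-3.343	-0.175	0.135	0.718	0.147
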