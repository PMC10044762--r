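contrast	time_h	gene	log2FC	padj	base_mean
drugA_vs_ctl	36	Tnf	2.1	0.001	210
drugA_vs_ctl	36	Nos2	1.4	0.01	95
drugA_vs_ctl	36	Il6	0.8	0.2	310
drugA_vs_ctl	36	Fpr2	-1.2	0.03	55
drugA_vs_ctl	36	Il10	-0.9	0.04	120
drugA_vs_ctl	36	Hk2	0.2	0.7	400
drugA_vs_ctl	120	Tnf	-1.5	0.02	140
drugA_vs_ctl	120	Nos2	-0.7	0.2	80
drugA_vs_ctl	120	Fpr2	-2.0	0.004	30
drugA_vs_ctl	120	Il10	-1.1	0.03	90
drugA_vs_ctl	120	Hk2	-0.4	0.5	380
drugB_vs_ctl	36	Tnf	0.3	0.6	205
drugB_vs_ctl	36	Nos2	0.5	0.4	90
drugB_vs_ctl	36	Il6	1.1	0.04	290
drugB_vs_ctl	36	Fpr2	0.6	0.3	60
drugB_vs_ctl	36	Il10	0.4	0.5	115
drugB_vs_ctl	120	Tnf	1.2	0.04	160
drugB_vs_ctl	120	Fpr2	2.4	0.001	70
drugB_vs_ctl	120	Il10	1.6	0.01	150
drugB_vs_ctl	120	Hif1a	1.3	0.02	220
drugB_vs_ctl	120	Hk2	0.9	0.04	420
drugB_vs_ctl	120	Il2rb	1.8	0.005	65
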