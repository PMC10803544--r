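gene_id	isoform	protein	carrier_count	cohort_size	pct_printed
FCGR2A	FCGR2A_XM_015113136.2	XP_014968622.2	192	206	93.2
FCGR2A	FCGR2A_XM_028846297.1	XP_028702130.1	109	206	52.9
FCGR2A	FCGR2A_NM_001257300.1	NP_001244229.1	86	206	41.7
FCGR2A	FCGR2A_XM_028846295.1	XP_028702128.1	62	206	30.1
FCGR2B	FCGR2B_XM_015113204.2	XP_014968690.1	201	206	97.6
FCGR2B	FCGR2B_XM_015113196.2	XP_014968682.1	196	206	95.1
FCGR2B	FCGR2B_NM_001271648.2	NP_001258577.2	9	206	4.4
FCGR2B	FCGR2B_NM_001257302.1	NP_001244231.1	1	206	0.48
FCGR3	FCGR3_NM_001271657.1	NP_001258586.1	201	206	97.6
FCGR3	FCGR3_XM_015113171.2	XP_014968657.2	141	206	68.4
FCGR3	FCGR3_XM_015113175.2	XP_014968661.2	134	206	65.0
FCGR3	FCGR3_NM_001271654.1	NP_001258583.1	4	206	1.94
FCGR3	FCGR3_NM_001271653.1	NP_001258582.1	3	206	1.46
FCGR3	FCGR3_NM_001271656.1	NP_001258585.1	3	206	1.46
FCGR3	FCGR3_NM_001271655.1	NP_001258584.1	2	206	0.97
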