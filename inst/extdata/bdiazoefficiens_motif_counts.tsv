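condition	motif	modified_position	mod_type	n_methylated	n_motifs	mean_qv	mean_coverage	mean_ipd
free_living	GANTC	2	m6A	33118	33196	136.16	129.93	4.61
free_living	CRAGGAT	6	m6A	4003	4005	196.26	130.19	6.29
free_living	CRAGGAT	1	m4C	613	4005	68.45	126.62	2.42
free_living	GAGA(N)6RTG	4	m6A	2080	2080	182.73	129.81	5.73
free_living	CAY(N)6TCTC	2	m6A	2079	2080	190.17	130.22	6.13
free_living	CCTTGAG	6	m6A	0	1700	NA	NA	NA
bacteroid	GANTC	2	m6A	32353	33196	84.99	62.89	5.07
bacteroid	CCTTGAG	6	m6A	1361	1700	57.77	66.75	4.07
bacteroid	CRAGGAT	6	m6A	3504	4005	53.47	64.67	3.46
bacteroid	GAGA(N)6RTG	4	m6A	1718	2080	50.72	63.95	3.27
bacteroid	CAY(N)6TCTC	2	m6A	1790	2080	50.69	64.13	3.37
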