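inital_value	chain	Spread value	Loss value	tox_begin value	tox_fin value	JQC_begin value	JQC_fin value	fin_value
86.93	DHCR24 [JQC]-UBC-CFL1	26.74	60.19	0.00	0.00	86.93	63.29	90.03
86.93	DHCR24 [JQC]-UBC-MAP2K1	25.54	61.39	0.00	0.00	86.93	60.45	85.99
86.93	DHCR24 [JQC]-UBC-ACTB	25.29	61.64	0.00	0.00	86.93	59.86	85.15
86.93	DHCR24 [JQC]-UBC-PTBP1	25.03	61.90	0.00	0.00	86.93	59.25	84.28
86.93	DHCR24 [JQC]-UBC-CSNK2A2 [JQC]	23.06	63.87	0.00	0.00	86.93	54.58	77.65
86.93	DHCR24 [JQC]-UBC-PPIA [JQC]	22.44	64.48	0.00	0.00	86.93	53.12	75.57
86.93	DHCR24 [JQC]-UBC-KDM2A [JQC]	22.18	64.75	0.00	0.00	86.93	52.50	74.68
86.93	DHCR24 [JQC]-UBC-RAF1 [JQC]	21.59	65.34	0.00	0.00	86.93	51.10	72.69
270.12	PGC-ULK2-CREB1 [JQC]	33.41	236.71	0.00	0.00	33.41	33.41	66.83
86.93	DHCR24 [JQC]-UBC-NRAS [JQC]	19.12	67.81	0.00	0.00	86.93	45.25	64.36
86.93	DHCR24 [JQC]-RBPJ-CREB1 [JQC]	13.75	73.18	0.00	0.00	86.93	50.52	64.27
65.71	PAM [JQC]-UBC-PSMD9	19.13	46.58	0.00	0.00	65.71	44.33	63.46
65.71	PAM [JQC]-UBC-POLD4	18.81	46.90	0.00	0.00	65.71	43.60	62.42
65.71	PAM [JQC]-FAU-EEF1A1 [JQC]	15.18	50.53	0.00	0.00	65.71	47.17	62.36
65.71	PAM [JQC]-UBC-DHDDS	18.61	47.10	0.00	0.00	65.71	43.13	61.74
270.12	PGC-CDK9 [JQC]-EWSR1	30.79	239.33	0.00	0.00	40.06	30.79	61.58
270.12	PGC-CDK9 [JQC]-RELA	30.27	239.85	0.00	0.00	40.06	30.27	60.54
65.71	PAM [JQC]-UBC-MARK2	17.56	48.15	0.00	0.00	65.71	40.70	58.27
65.71	PAM [JQC]-UBC-STAT3	17.51	48.20	0.00	0.00	65.71	40.58	58.10
86.93	DHCR24 [JQC]-UBC-LMNA [TOX]	23.37	63.55	23.37	23.37	86.93	55.32	55.32
86.93	DHCR24 [JQC]-TP53 [TOX]-SRSF1	16.94	69.98	27.22	16.94	86.93	54.11	54.11
86.93	DHCR24 [JQC]-UBC-ACTN4 [TOX]	21.66	65.27	21.66	21.66	86.93	51.26	51.26
65.71	PAM [JQC]-CALM1 [JQC]-RELA	13.53	52.18	0.00	0.00	65.71	36.22	49.75
65.71	PAM [JQC]-CALM1 [JQC]-TRAF6	13.52	52.19	0.00	0.00	65.71	36.21	49.73
86.93	DHCR24 [JQC]-UBC-SRRM2	14.60	72.32	0.00	0.00	86.93	34.57	49.17
86.93	DHCR24 [JQC]-TP53 [TOX]-BAX	15.03	71.90	27.22	15.03	86.93	48.01	48.01
270.12	PGC-CDK9 [JQC]-MAPK3	23.90	246.22	0.00	0.00	40.06	23.90	47.80
65.71	PAM [JQC]-UBC-SOD2	13.54	52.17	0.00	0.00	65.71	31.38	44.93
86.93	DHCR24 [JQC]-TP53 [TOX]-XRCC1	14.04	72.89	27.22	14.04	86.93	44.84	44.84
272.62	MMP1-UBC-CSNK2A2 [JQC]	20.97	251.65	0.00	0.00	20.97	20.97	41.94
272.62	MMP1-UBC-MCL1 [JQC]	20.84	251.78	0.00	0.00	20.84	20.84	41.68
272.62	MMP1-UBC-KDM2A [JQC]	20.17	252.45	0.00	0.00	20.17	20.17	40.33
272.62	MMP1-UBC-GAPDH [JQC]	20.12	252.50	0.00	0.00	20.12	20.12	40.23
272.62	MMP1-UBC-RAF1 [JQC]	19.63	252.98	0.00	0.00	19.63	19.63	39.26
86.93	DHCR24 [JQC]-TP53 [TOX]-SETD2	12.18	74.75	27.22	12.18	86.93	38.88	38.88
270.12	PGC-CDK9 [JQC]-CDK2 [JQC]	19.14	250.98	0.00	0.00	40.06	19.14	38.27
86.93	DHCR24 [JQC]-MDM2 [TOX][JQC]-EEF1A1 [JQC]	3.71	83.22	11.75	3.71	86.93	27.42	27.42
86.93	DHCR24 [JQC]-UBC-APOE [TOX]	10.46	76.47	10.46	10.46	86.93	24.75	24.75
65.71	PAM [JQC]-UBC-F3 [TOX][JQC]	10.50	55.21	10.50	10.50	65.71	24.33	24.33
18.84	PPP1CC [JQC]-CDK2 [JQC]-HNRNPC	9.06	9.78	0.00	0.00	18.84	12.78	21.84
86.93	DHCR24 [JQC]-MDM2 [TOX][JQC]-MTOR	2.93	84.00	11.75	2.93	86.93	21.70	21.70
18.84	PPP1CC [JQC]-ATP6V1A-PSMD2	8.14	10.71	0.00	0.00	18.84	12.28	20.42
39.05	CD81-UBC-CASP3 [JQC]	10.15	28.90	0.00	0.00	10.15	10.15	20.30
39.05	CD81-CD4 [JQC]-CD44	10.12	28.93	0.00	0.00	19.04	10.12	20.23
39.05	CD81-UBC-CASP7 [JQC]	10.09	28.96	0.00	0.00	10.09	10.09	20.17
39.05	CD81-UBC-PAM [JQC]	8.10	30.95	0.00	0.00	8.10	8.10	16.20
18.84	PPP1CC [JQC]-CSNK2A1 [JQC]-CCDC6	6.53	12.31	0.00	0.00	18.84	9.60	16.14
18.84	PPP1CC [JQC]-UBC-WDTC1	6.00	12.85	0.00	0.00	18.84	10.14	16.14
18.77	KDR [JQC]-BTRC-NFKB1 [JQC]	3.62	15.15	0.00	0.00	18.77	11.28	14.90
18.77	KDR [JQC]-BTRC-AXIN1	3.61	15.16	0.00	0.00	18.77	11.24	14.85
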