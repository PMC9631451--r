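id	herb	name	mw	hdon	hacc	rbn	fsp3	gi	herg
MID002175	LGT	Dehydroabietlc acid	300.44	1	2	2	0.65	High	low_risk
MID002604	LGT	1,8-Dihydroxy-4-hydroxymethyl anthraquinone	270.24	3	5	1	0.07	High	medium_risk
MID003059	LGT	13,14-Epoxide 9,11,12-hydroxytriptolide	378.42	3	7	1	0.85	High	low_risk
MID004372	LGT	16-Hydroxy-19,20-epoxy-kaurane	304.47	1	2	0	1	High	low_risk
MID004566	LGT	16-Hydroxytriptolide	376.4	2	7	2	0.85	High	low_risk
MID004591	LGT	Hypolide methyl ether	326.43	0	3	2	0.57	High	medium_risk
MID004875	LGT	Isoneotriptophenolide	342.43	1	4	2	0.57	High	low_risk
MID005713	LGT	(+)-Medioresinol	388.41	2	7	5	0.43	High	medium_risk
MID006737	LGT	Neotriptophenolide	342.43	1	4	2	0.57	High	low_risk
MID008653	LGT	DL-Syringaresinol	418.44	2	8	6	0.45	High	low_risk
MID009364	LGT	Triptonoterpene; 14-Hydroxy-abieta-8,11,13-trien-3-one	300.44	1	2	1	0.65	High	low_risk
MID009365	LGT	Triptonoterpenol	346.46	2	4	3	0.67	High	low_risk
MID009708	LGT	Wilforonide	220.26	0	3	0	0.69	High	low_risk
MID009909	LGT	DIBP	278.34	0	4	8	0.5	High	low_risk
MID010186	LGT	succinic acid	118.09	2	4	3	0.5	High	low_risk
MID010204	LGT	syringaresinol	418.44	2	8	6	0.45	High	low_risk
MID010234	LGT	(+)-Syringaresinol	418.44	2	8	6	0.45	High	low_risk
MID010260	LGT	kaempferol	286.24	4	6	1	0	High	medium_risk
MID010507	LGT	DBP	278.34	0	4	10	0.5	High	low_risk
MID011265	LGT	protocatechualdehyde	138.12	2	3	1	0	High	low_risk
MID011615	LGT	Cedar acid	198.17	2	5	3	0.22	High	low_risk
MID011639	LGT	HX	136.11	2	3	0	0	High	medium_risk
MID011860	LGT	40957-99-1	388.41	2	7	5	0.43	High	medium_risk
MID012941	LGT	2,5-Dimethoxybenzoquinone	168.15	0	4	2	0.25	High	medium_risk
MID012951	LGT	(+)-Medioresinol di-O-beta-D-glucopyranoside_qt	388.41	2	7	5	0.43	High	medium_risk
MID012953	LGT	81827-74-9	342.43	1	4	2	0.57	High	low_risk
MID012954	LGT	(1R,4aR,10aS)-5-hydroxy-1-(hydroxymethyl)-7-isopropyl-8-methoxy-1,4a-dimethyl-4,9,10,10a-tetrahydro-3H-phenthren-2-one	346.46	2	4	3	0.67	High	low_risk
MID012956	LGT	triptolide	360.4	1	6	1	0.85	High	low_risk
MID012957	LGT	Tripchlorolide	396.86	2	6	1	0.85	High	low_risk
MID012960	LGT	Tripdiolide	376.4	2	7	1	0.85	High	low_risk
MID012961	LGT	Triptonide	344.36	0	6	1	0.79	High	low_risk
MID012965	LGT	Tryptophenolide	312.4	1	3	1	0.55	High	low_risk
MID012968	LGT	5,8-Dihydroxy-7-(4-hydroxy-5-methyl-coumarin-3)-coumarin	352.29	3	7	1	0.05	High	medium_risk
MID012969	LGT	HRP	220.22	4	4	3	0.18	High	medium_risk
MID012972	LGT	8-Epilpganic acid_qt	214.22	3	5	1	0.7	High	low_risk
MID012975	LGT	Canin	278.3	1	5	0	0.8	High	low_risk
MID012977	LGT	Celafurine	369.46	2	4	3	0.43	High	medium_risk
MID012983	LGT	Dunnisinin	226.23	1	5	2	0.73	High	low_risk
MID012985	LGT	trans-Nepetalactone	166.22	0	2	0	0.7	High	low_risk
MID012986	LGT	Isoxanthohumol	354.4	2	5	4	0.29	High	medium_risk
MID012987	LGT	Neouralenol	370.35	5	7	3	0.15	High	medium_risk
MIDNA001	LGT	[(3aR,4S,6E,9S,10Z,11aR)-9-hydroxy-6,10-dimethyl-3-methylene-2-oxo-3a,4,5,8,9,11a-hexahydrocyclodeca [b]furan-4-yl] (E)-2-methylbut-2-enoate	346.42	1	5	3	0.5	High	medium_risk
MID012992	LGT	Tripdiotolnide	360.4	2	6	1	0.7	High	low_risk
MID012993	LGT	Hypodiolide A	318.45	1	3	0	0.95	High	low_risk
MID012996	LGT	Norathyriol	260.2	4	6	0	0	High	low_risk
MID012997	LGT	Triptinin B	314.42	2	3	2	0.55	High	low_risk
MID012999	LGT	Triptoditerpenic acid B	328.45	1	3	3	0.57	High	low_risk
MID013005	LGT	(3E,7E)-2alpha,10beta,13alpha-Triacetoxy-5alpha,20-dihydroxy-3,8-seco-taxa-3,7,11-trien-9-one	492.56	2	9	7	0.62	High	ambiguous
MID013011	LGT	Triptolidenol	376.4	2	7	1	0.85	High	low_risk
MID013012	LGT	Triptonide	358.39	0	6	1	0.8	High	low_risk
MID013013	LGT	Triptonoditerpenic acid	344.44	2	4	3	0.57	High	low_risk
MID013014	LGT	11-Hydroxy-14,15alpha-epoxytabersonine	368.43	2	5	3	0.57	High	low_risk
MID013015	LGT	Triptonoterpene methyl ether	330.46	1	3	2	0.67	High	low_risk
MID013016	LGT	Triptonoterpene	300.44	1	2	1	0.65	High	low_risk
MID013031	LGT	Wilfordic acid	223.23	2	5	5	0.36	High	low_risk
MID013037	LGT	104331-87-5	220.26	0	3	0	0.69	High	low_risk
MID013040	LGT	Wilsonine	343.42	0	5	3	0.6	High	low_risk
MID013047	LGT	99694-86-7	376.4	2	7	1	0.85	High	low_risk
MID013048	LGT	TRIPTONOLIDE	326.39	1	4	1	0.5	High	low_risk
MID013051	LGT	(2R,3R,4S)-4-(4-hydroxy-3-methoxy-phenyl)-7-methoxy-2,3-dimethylol-tetralin-6-ol	360.4	4	6	5	0.4	High	medium_risk
MID013722	LGT	caffeine	194.19	0	3	0	0.38	High	medium_risk
MID014181	LGT	Zhebeiresinol	280.27	1	6	3	0.5	High	low_risk
MID014393	LGT	fraxetin	208.17	2	5	1	0.1	High	low_risk
MID016058	LGT	(2R,3R,4S)-4-(4-hydroxy-3,5-dimethoxy-phenyl)-5,7-dimethoxy-2,3-dimethylol-tetralin-6-ol	420.45	4	8	7	0.45	High	low_risk
MID016077	LGT	4-[(1R,3aS,4R,6aS)-4-(4-hydroxy-3,5-dimethoxyphenyl)-1,3,3a,4,6,6a-hexahydrofuro [4,3-c]furan-1-yl]-2,6-dimethoxyphenol	418.44	2	8	6	0.45	High	low_risk
MID017234	LGT	3-hydroxy-1-(3,5-dimethoxy-4-hydroxyphenyl)propan-1-one	226.23	2	5	5	0.36	High	low_risk
MID018996	LGT	3,3′-bis-(3,4-dihydro-4-hydroxy-6-methoxy)-2H-1-benzopyran	358.39	2	6	3	0.4	High	medium_risk
MID022242	LGT	Antiarol	184.19	1	4	3	0.33	High	low_risk
MID004896	JQC	Isopinocamphone	152.23	0	1	0	0.9	High	low_risk
MID005770	JQC	Menthol	156.27	1	1	1	1	High	low_risk
MID005771	JQC	Menthol-b	156.27	1	1	1	1	High	low_risk
MID007428	JQC	L-Pinocamphone	152.23	0	1	0	0.9	High	low_risk
MID009860	JQC	apigenin	270.24	3	5	1	0	High	medium_risk
MID009925	JQC	ent-Epicatechin	290.27	5	6	1	0.2	High	medium_risk
MID009949	JQC	quercetin	302.24	5	7	1	0	High	medium_risk
MID009953	JQC	PHB	138.12	2	3	1	0	High	low_risk
MID009966	JQC	Nol	142.24	0	1	7	0.89	High	low_risk
MID009968	JQC	(L)-alpha-Terpineol	154.25	1	1	1	0.8	High	low_risk
MID009980	JQC	CAM	152.23	0	1	0	0.9	High	low_risk
MID010041	JQC	(R)-lilool	154.25	1	1	4	0.6	High	low_risk
MID010093	JQC	Rhamnocitrin	300.26	3	6	2	0.06	High	medium_risk
MID010193	JQC	isorhamnetin	316.26	4	7	2	0.06	High	medium_risk
MID010260	JQC	kaempferol	286.24	4	6	1	0	High	medium_risk
MID010435	JQC	O-Methylthymol	164.24	0	1	2	0.45	High	medium_risk
MID010526	JQC	patchouli alcohol	222.37	1	1	0	1	High	low_risk
MID010546	JQC	l-Menthone	154.25	0	1	1	0.9	High	low_risk
MID010700	JQC	Cedrol	222.37	1	1	0	1	High	low_risk
MID011127	JQC	o-Acetyl-p-cresol	150.17	1	2	1	0.22	High	low_risk
MID011208	JQC	49070_FLUKA	222.37	1	1	0	1	High	low_risk
MID011498	JQC	acacetin	284.26	2	5	2	0.06	High	medium_risk
MID011502	JQC	Perillyl alcohol	152.23	1	1	2	0.6	High	low_risk
MID011777	JQC	Pulegone	152.23	0	1	0	0.7	High	low_risk
MID011806	JQC	(-)-Caryophyllene oxide	220.35	0	1	0	0.87	High	medium_risk
MID011844	JQC	thymol	150.22	1	1	1	0.4	High	low_risk
MID012135	JQC	Hesperetin	302.28	3	6	2	0.19	High	medium_risk
MID012156	JQC	beta-Ionone	192.3	0	1	2	0.62	High	low_risk
MID017581	JQC	2-Hexanoylfuran	166.22	0	2	5	0.5	High	low_risk
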