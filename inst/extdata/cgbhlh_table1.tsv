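no	gene_name	orf_bp	gene_id	at_homolog	abbr_name	identity_pct
1	CgbHLH2	1869	Cg5g002660	AT1G63650	EGL3	52.09
2	CgbHLH3	1512	Cg5g034370	AT4G16430	JAM3	58.3
3	CgbHLH6	2064	CgUng000770	AT1G32640	JAI1	61.74
4	CgbHLH8	2229	Cg5g013200	AT1G09530	PIF3	44.38
5	CgbHLH9	1632	Cg7g012190	AT2G43010	PIF4	44.07
6	CgbHLH10	1071	Cg9g023740	AT2G31220	NA	46.5
7	CgbHLH12	1974	Cg5g042050	AT4G00480	MYC1	49.49
8	CgbHLH13	1482	Cg5g040610	AT1G01260	JAM2	57.11
9	CgbHLH14.1	1551	Cg5g040200	AT4G00870	NA	47.04
10	CgbHLH14.2	1563	Cg5g000450	AT4G00870	NA	37.07
11	CgbHLH15	1764	Cg5g032930	AT2G20180	PIL5	46.61
12	CgbHLH16	1386	Cg5g043840	AT4G00050	UNE10	59.43
13	CgbHLH18	783	Cg5g017710	AT2G22750	NA	41.44
14	CgbHLH21.1	1785	Cg8g001500	AT2G16910	AMS	48.72
15	CgbHLH21.2	1419	Cg7g019250	AT2G16910	AMS	36.78
16	CgbHLH22	585	Cg2g040910	AT4G21330	DYT1	43.92
17	CgbHLH25.1	570	Cg8g002160	AT4G37850	NA	49.25
18	CgbHLH25.2	1017	Cg1g007240	AT4G37850	NA	44.83
19	CgbHLH25.3	426	Cg8g002170	AT4G37850	NA	44.56
20	CgbHLH25.4	1107	Cg1g007260	AT4G37850	NA	44.04
21	CgbHLH29.1	210	Cg8g019060	AT2G28160	FIT	64.41
22	CgbHLH29.2	222	Cg8g019160	AT2G28160	FIT	61.9
23	CgbHLH29.3	489	Cg8g018990	AT2G28160	FIT	52.0
24	CgbHLH29.4	969	Cg8g019240	AT2G28160	FIT	51.16
25	CgbHLH29.5	501	Cg8g019040	AT2G28160	FIT	50.49
26	CgbHLH29.6	633	Cg8g019200	AT2G28160	FIT	49.54
27	CgbHLH29.7	237	Cg8g019020	AT2G28160	FIT	49.25
28	CgbHLH29.8	660	Cg8g019140	AT2G28160	FIT	48.15
29	CgbHLH29.9	651	Cg8g018940	AT2G28160	FIT	47.27
30	CgbHLH29.10	1416	Cg8g019230	AT2G28160	FIT	37.17
31	CgbHLH29.11	903	Cg8g018890	AT2G28160	FIT	33.15
32	CgbHLH30	798	Cg2g043260	AT1G68810	ABS5	41.67
33	CgbHLH31	753	Cg7g020320	AT1G59640	ZCW32	51.95
34	CgbHLH32	789	Cg7g014890	AT3G25710	TMO5	58.65
35	CgbHLH33.1	1659	Cg7g011080	AT1G12860	ICE2	57.28
36	CgbHLH33.2	1443	Cg2g009820	AT1G12860	ICE2	55.8
37	CgbHLH35	747	Cg4g021000	AT5G57150	NA	57.2
38	CgbHLH36.1	741	Cg9g025850	AT5G51780	NA	53.85
39	CgbHLH36.2	744	Cg5g009400	AT5G51780	NA	42.77
40	CgbHLH36.3	726	Cg9g025870	AT5G51780	NA	38.69
41	CgbHLH36.4	1122	Cg3g014280	AT5G51780	NA	25.81
42	CgbHLH37	807	Cg1g002590	AT3G50330	HEC2	53.88
43	CgbHLH39	762	Cg9g016290	AT3G56980	ORG3	47.5
44	CgbHLH41	1599	Cg4g008800	AT5G56960	NA	29.22
45	CgbHLH42	2073	Cg5g035630	AT4G09820	TT8	56.51
46	CgbHLH43	462	Cg1g025450	AT5G09750	HEC3	66.92
47	CgbHLH44	1200	Cg1g004400	AT1G18400	BEE1	21.48
48	CgbHLH45	555	Cg9g004620	AT3G06120	MUTE	65.03
49	CgbHLH46	1761	Cg5g012000	AT5G08130	BIM1	53.08
50	CgbHLH47	729	Cg5g003170	AT3G47640	PYE	51.79
51	CgbHLH48	1227	Cg9g022350	AT2G42300	NA	59.32
52	CgbHLH49	1680	Cg7g015600	AT1G68920	CIB1	54.17
53	CgbHLH50	798	Cg5g022610	AT1G73830	BEE3	55.27
54	CgbHLH51	843	Cg7g002190	AT2G40200	NA	42.34
55	CgbHLH52	939	Cg2g038660	AT1G30670	NA	42.51
56	CgbHLH57	1299	Cg5g039930	AT4G01460	NA	51.96
57	CgbHLH62	1665	Cg6g008950	AT3G07340	CIB3	53.27
58	CgbHLH63	1215	Cg8g007040	AT4G34530	CIB1	46.28
59	CgbHLH68	1023	Cg1g014350	AT4G29100	NA	51.43
60	CgbHLH69.1	633	Cg3g010300	AT4G30980	LRL2	55.43
61	CgbHLH69.2	1044	Cg4g024560	AT4G30980	LRL2	52.04
62	CgbHLH72	1155	Cg5g010830	AT5G61270	PIF7	47.52
63	CgbHLH73.1	1233	Cg1g005520	AT5G67110	ALC	49.15
64	CgbHLH73.2	4401	Cg5g039380	AT5G67110	ALC	29.05
65	CgbHLH73.3	915	Cg1g019630	AT5G67110	ALC	26.42
66	CgbHLH74	1284	Cg3g013130	AT1G10120	CIB4	49.3
67	CgbHLH75.1	717	Cg2g036150	AT1G25330	CES	52.2
68	CgbHLH75.2	1095	Cg6g019500	AT1G25330	CES	39.9
69	CgbHLH77	1455	Cg9g014180	AT3G23690	CIL2	47.21
70	CgbHLH79	840	Cg5g004140	AT5G62610	NA	59.71
71	CgbHLH80	765	Cg3g020720	AT1G35460	FBH1	63.68
72	CgbHLH82	1563	Cg4g018170	AT5G58010	LRL3	43.38
73	CgbHLH83	888	Cg6g018550	AT1G66470	RHD6	48.46
74	CgbHLH85.1	1089	Cg8g003130	AT4G33880	RSL2	51.39
75	CgbHLH85.2	1104	Cg3g012730	AT4G33880	RSL2	45.74
76	CgbHLH87.1	1296	Cg1g009170	AT3G21330	NA	52.65
77	CgbHLH87.2	513	Cg6g009450	AT3G21330	NA	47.87
78	CgbHLH88	822	Cg3g021250	AT5G67060	HEC1	50.93
79	CgbHLH91	1428	Cg5g045050	AT2G31210	NA	45.32
80	CgbHLH93.1	1065	Cg1g007400	AT5G65640	NFL	52.13
81	CgbHLH93.2	1155	Cg3g013530	AT5G65640	NFL	46.11
82	CgbHLH94	957	Cg1g008260	AT1G22490	NA	46.89
83	CgbHLH95.1	939	Cg8g004350	AT1G49770	RGE1	42.18
84	CgbHLH95.2	804	Cg3g021160	AT1G49770	RGE1	41.02
85	CgbHLH95.3	729	Cg2g044520	AT1G49770	RGE1	24.66
86	CgbHLH96.1	993	Cg3g014510	AT1G72210	NA	56.62
87	CgbHLH96.2	906	Cg2g030740	AT1G72210	NA	51.72
88	CgbHLH97	1287	Cg9g012540	AT3G24140	FMA	60.67
89	CgbHLH98	966	Cg9g028240	AT5G53210	SPCH	61.29
90	CgbHLH102.1	1029	Cg7g015780	AT1G69010	BIM2	60.19
91	CgbHLH102.2	1026	Cg6g020770	AT1G69010	BIM2	44.37
92	CgbHLH104	648	Cg9g007860	AT4G14410	NA	64.62
93	CgbHLH105.1	714	Cg2g023210	AT5G54680	ILR3	73.16
94	CgbHLH105.2	711	Cg2g017780	AT5G54680	ILR3	65.18
95	CgbHLH105.3	711	Cg2g040740	AT5G54680	ILR3	62.11
96	CgbHLH107.1	717	Cg6g017840	AT3G56770	NA	59.26
97	CgbHLH107.2	786	Cg3g014080	AT3G56770	NA	37.04
98	CgbHLH107.3	846	Cg2g008600	AT3G56770	NA	35.87
99	CgbHLH110.1	1299	Cg3g023160	AT1G27660	NA	51.35
100	CgbHLH110.2	1104	CgUng019530	AT1G27660	NA	48.1
101	CgbHLH112	1479	Cg2g040950	AT1G61660	NA	44.04
102	CgbHLH113	819	Cg8g003580	AT3G19500	NA	45.71
103	CgbHLH120	537	Cg9g025860	AT5G51790	NA	47.46
104	CgbHLH121	1029	CgUng005820	AT3G19860	NA	61.39
105	CgbHLH122	1296	Cg2g002540	AT1G51140	FBH3	45.14
106	CgbHLH123	1377	Cg2g022720	AT3G20640	NA	49.59
107	CgbHLH128	1116	Cg5g028960	AT1G05805	AKS2	55.06
108	CgbHLH130.1	2334	Cg9g022410	AT2G42280	FBH4	57.14
109	CgbHLH130.2	1287	Cg7g023040	AT2G42280	FBH4	45.99
110	CgbHLH137.1	1116	Cg7g010980	AT5G50915	NA	45.96
111	CgbHLH137.2	837	Cg7g022310	AT5G50915	NA	43.89
112	CgbHLH138	1542	Cg1g007950	AT2G31215	NA	28.0
113	CgbHLH144	609	Cg1g004390	AT1G29950	SACL3	23.28
114	CgbHLH153	435	Cg5g026370	AT1G05710	NA	66.42
115	CgbHLH154.1	933	Cg1g012580	AT2G31730	NA	47.0
116	CgbHLH154.2	735	Cg7g004740	AT2G31730	NA	36.36
117	CgbHLH154.3	1107	Cg5g035790	AT2G31730	NA	24.68
118	CgbHLH155	2250	Cg5g034200	AT2G31280	LHL2	47.44
119	CgbHLH160	999	Cg3g004340	AT1G71200	CITF1	40.58
120	CgbHLH162.1	570	Cg2g042210	AT4G20970	NA	42.93
121	CgbHLH162.2	345	Cg2g005390	AT4G20970	NA	38.16
122	CgbHLH162.3	279	Cg2g005350	AT4G20970	NA	37.84
123	CgbHLH162.4	549	Cg5g004810	AT4G20970	NA	35.23
124	CgbHLH162.5	498	Cg2g005320	AT4G20970	NA	33.54
125	CgbHLH162.6	462	Cg2g005400	AT4G20970	NA	33.56
126	CgbHLH162.7	666	Cg2g015830	AT4G20970	NA	31.28
127	CgbHLH162.8	498	Cg2g005380	AT4G20970	NA	31.06
128	CgbHLH162.9	420	Cg2g005340	AT4G20970	NA	33.33
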