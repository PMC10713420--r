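accession	gene	sequence	mass_printed	fold_change	p_value	direction
P63269	Actg2	VITIGNERF	1352	12.197	0.0001557	up
A0A0H2UHM7	LOC100909441	EPTVIDEVRTGTY	1783	13.684	7.71e-05	up
Q4JEI8	Defa6	DEDQDVSVSF	1444	13.062	0.0016019	up
P85108	Tubb2a	IDPTGSYHGDSDLQLE	2050	12.030	0.00077955	up
P06302	Ptma	DGDEDEEAEAPTGKRVAEDDE	2884	12.057	3.67e-06	up
A0A0G2K6S9	Myh11	AQKGQLSDDEKF	2015	15.550	8.32e-06	up
C0JPT7	Flna	KVEYTPYEEGVHSVD	2359	12.187	9.37e-05	up
Q4QQV0	Tubb6	NATLSVHQLVENTDETY	2238	12.938	1.20e-06	up
A0A0G2JTV2	Cald1	SVPDEESKPATANAQVEG	2436	13.035	0.00122112	up
O35413	Sorbs2	TSPGRADLPGSSSTFTT	1985	13.191	0.00155698	up
D3ZX87		KNLQTVNVDEN	1881	14.296	6.84e-05	up
A0A0G2JSV6	Hba-a2	FAAFPTTKTY	1754	14.558	0.00056143	up
P63269	Actg2	QPSFIGMESAGIHETTY	2187	14.849	4.62e-05	up
P11980	Pkm	PKPDSEAGTAFIQTQQL	2438	15.3097	0.00013413	up
D3ZHA0	Flnc	IVDPNVDEHSVM	1674	15.8012	8.61e-05	up
D3ZHA0	Flnc	IVDPNVDEHSVMTY	1938	16.201	3.95e-07	up
A0A0H2UHM7	LOC100909441	SDKTIGGGDDSFNTF	2168	16.733	0.00068066	up
D3ZYS7	G3bp1	DVAPAQEDLRTF	1665	16.810	0.00018704	up
Q4JEI2	Defal1	DPIQEAEEETKTEEQPADEDQDVSVSF	3673	23.803	8.75e-07	up
G3V7C6	Tubb4b	VPSPKVSDTVVEPY	2124	40.356	0.00031686	up
P63269	Actg2	VFPSIVGR	1275	0.040	6.41e-05	down
P63269	Actg2	MQKEITALAPSTMK	2460	0.065	3.86e-05	down
F1M853	Rrbp1	TLQEQLENGPNTQLA	1959	0.072	8.47e-06	down
P63269	Actg2	GILTLKYPIEHG	1962	0.072	5.68e-05	down
Q5BJ93	Eno1	GDDLTVTNPK	1667	0.073	7.15e-05	down
Q10758	Krt8	LNPLKLEVDPNIQAV	2270	0.073	9.42e-07	down
P85834	Tufm	GTVVTGTLER	1336	0.080	2.83e-06	down
P63039	Hspd1	SIVPALEIANAHR	1695	0.080	0.00025387	down
P10111	Ppia	EGMSIVEAMERFGS	1862	0.088	0.0002383	down
Q9QXQ0	Actn4	ALDFIASK	1472	0.091	0.00010306	down
P63039	Hspd1	QSKPVTTPEEIAQ	2035	0.092	1.60e-07	down
A0A0G2KAJ7	Col12a1	ITYQPSTGEGNEQTTTVGGR	2399	0.092	0.00032739	down
Q10758	Krt8	KLEVDPNIQAV	1833	0.098	1.01e-05	down
A0A0H2UHM5	Pdia3	TADGIVSHL	1216	0.106	8.29e-06	down
B0K010	Txndc17	ITAVPTLLK	1563	0.111	0.00014108	down
P34058	Hsp90ab1	KHLEINPDHPIVETLR	2518	0.111	8.69e-05	down
P63269	Actg2	GVMVGMGQKDSYVG	2051	0.112	0.00107894	down
A0A0H2UHM7	LOC100909441	YAPVISAEK	1585	0.114	2.36e-06	down
Q10758	Krt8	KLEVDPNIQA	1734	0.115	2.81e-06	down
P63269	Actg2	GYSFVTTAEREIV	1775	0.120	0.00139115	down
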