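sequence	gene	start	end	domain_start	domain_end	domain_name	direction
VITIGNERF	Actg2	248	256	3	376	Actin	up
EPTVIDEVRTGTY	LOC100909441	71	83	48	245	Tubulin	up
DEDQDVSVSF	Defa6	37	46	1	50	Defensin_propep	up
IDPTGSYHGDSDLQLE	Tubb2a	30	45	3	212	Tubulin	up
DGDEDEEAEAPTGKRVAEDDE	Ptma	76	96	42	101	Asp/Glu-rich (acidic)	up
KVEYTPYEEGVHSVD	Flna	1318	1332	1250	1349	Filamin	up
NATLSVHQLVENTDETY	Tubb6	184	200	47	244	Tubulin	up
SVPDEESKPATANAQVEG	Cald1	144	161	102	623	Caldesmon	up
FAAFPTTKTY	Hba-a2	34	43	3	142	Globin	up
QPSFIGMESAGIHETTY	Actg2	264	280	3	376	Actin	up
IVDPNVDEHSVM	Flnc	241	252	160	263	Calponin-homology (CH) 2	up
IVDPNVDEHSVMTY	Flnc	241	254	160	263	Calponin-homology (CH) 2	up
SDKTIGGGDDSFNTF	LOC100909441	38	41	2	213	Tubulin	up
DPIQEAEEETKTEEQPADEDQDVSVSF	Defal1	20	46	1	51	Defensin_propep	up
VPSPKVSDTVVEPY	Tubb4b	273	286	223	347	Tubulin	up
VFPSIVGRP	Actg2	31	39	3	376	Actin	down
MQKEITALAPSTMK	Actg2	314	327	3	376	Actin	down
GILTLKYPIEHG	Actg2	64	75	3	376	Actin	down
GDDLTVTNPK	Eno1	317	326	142	431	Enolase_C	down
LNPLKLEVDPNIQAV	Krt8	73	87	2	87	Keratin_2_head	down
GTVVTGTLER	Tufm	272	281	272	341	GTP_EFTU_D2	down
SIVPALEIANAHR	Hspd1	255	268	47	550	Cpn60_TCP1	down
EGMSIVEAMERFGS	Ppia	134	147	7	163	PPIase cyclophilin-type	down
ALDFIASK	Actn4	115	122	50	154	Calponin-homology (CH) 1	down
QSKPVTTPEEIAQ	Hspd1	158	170	47	550	Cpn60_TCP1	down
ITYQPSTGEGNEQTTTVGGR	Col12a1	1787	1806	1757	1851	Fibronectin type-III	down
KLEVDPNIQAV	Krt8	77	87	2	87	Keratin_2_head	down
TADGIVSHL	Pdia3	125	133	31	135	Thioredoxin	down
ITAVPTLLK	Txndc17	90	98	9	122	DUF953	down
KHLEINPDHPIVETLR	Hsp90ab1	624	639	620	723	Interaction with NR1D1	down
GVMVGMGQKDSYVG	Actg2	43	56	3	376	Actin	down
YAPVISAEK	A0A0H2UHM7	271	279	247	392	Tubulin_C	down
KLEVDPNIQA	Krt8	77	86	2	87	Keratin_2_head	down
GYSFVTTAEREIV	Actg2	198	210	3	376	Actin	down
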