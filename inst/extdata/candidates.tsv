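name	sequence	table1_sequence	fold_change	p_value	aliphatic_index	gravy	half_life_h
Actg2-1	VITIGNERF	VITIGNERF	12.197	0.0001557	118.89	0.378	100
Actg2-2	QPSFIGMESAGIHETTY	QPSFIGMESAGIHETTY	14.849	4.62e-05	51.76	-0.288	0.8
Actg2-3	VFPSIVGRP	VFPSIVGR	0.040	6.41e-05	107.78	0.756	100
Actg2-4	MQKEITALAPSTMK	MQKEITALAPSTMK	0.065	3.86e-05	70	-0.207	30
Actg2-5	GILTLKYPIEHG	GILTLKYPIEHG	0.072	5.68e-05	130	0.133	30
Actg2-6	GVMVGMGQKDSYVG	GVMVGMGQKDSYVG	0.112	0.00107894	62.14	0.129	30
Actg2-7	GYSFVTTAEREIV	GYSFVTTAEREIV	0.120	0.00139115	82.31	0.162	30
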