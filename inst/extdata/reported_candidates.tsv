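species	receptor_class	category	arrangement	gene_id	annotation	l2fc_1	l2fc_2	l2fc_3
E_cornigera	SR	SR_B	TM + CD36 + TM	GBRW01136834.1	Scavenger receptor class B member 1	2.41	1.43	NA
E_cornigera	SR	SR_E_like	TM + CTLD	GBRW01100272.1	Perlucin	3.04	1.32	NA
E_cornigera	SR	C_type_lectin	CTLD + CTLD + TM	GBRW01106608.1	C-type mannose receptor 2	2.53	8.50	NA
E_cornigera	SR	C_type_lectin	CTLD + CTLD + TM	GBRW01166191.1	C-type mannose receptor 2	2.11	1.15	NA
E_cornigera	SR	C_type_lectin	CTLD + CTLD + TM	GBRW01163094.1	Versican core protein	1.22	2.28	NA
E_cornigera	SR	C_type_lectin	TM + CTLD + CTLD + TM	GBRW01019759.1	Snaclec agglucetin subunit beta-1	1.69	1.17	NA
E_cornigera	TSR	TSR_noTM	TSP1	GBRW01123401.1	Hemicentin-1	3.24	2.69	NA
E_timida	SR	SR_E_like	TM + CTLD	GBRM01064602.1	Collectin-10	2.66	3.54	2.08
E_timida	SR	SR_E_like	TM + CTLD	GBRM01009636.1	C-type lectin 37 Da	2.80	2.54	6.14
E_timida	SR	SR_E_like	TM + CTLD	GBRM01066486.1	C-type lectin 37 Da	3.87	3.66	6.09
E_timida	SR	SR_E_like	TM + CTLD	GBRM01066478.1	Perlucin	3.69	3.92	4.63
E_timida	SR	SR_E_like	TM + CTLD	GBRM01039872.1	C-type mannose receptor 2	2.90	2.61	2.36
E_timida	SR	C_type_lectin	TM + CTLD + TM	GBRM01017414.1	Collectin-12	3.58	1.73	2.72
E_timida	TSR	ADAMTS_like	TSP1 + TSP1 + I-set + PLAC	GBRM01039431.1	Protein madd-4	8.92	9.47	10.06
E_chlorotica	SR	SR_B	TM + CD36 + TM	c104938_g1_i1_1-2480	Lysosome membrane protein 2	2.02	-2.12	1.33
E_chlorotica	SR	SR_B	TM + CD36 + TM	c128999_g1_i3_1-4140	Scavenger receptor class B member 1	2.58	-0.38	1.90
E_chlorotica	SR	C_type_lectin	CTLD + CTLD + TM	c119366_g1_i1_1-1981	Snaclec B1	1.10	-0.05	3.17
E_chlorotica	SR	C_type_lectin	CTLD + CTLD + TM	c124460_g1_i2_1-2516	Secretory phospholipase A2 receptor	1.68	0.48	2.95
E_chlorotica	TSR	TSR_other	VWA + TSP1 + VWA	c108772_g2_i1_27-1786	Collagen alpha-5 chain	1.05	2.00	-1.55
E_chlorotica	TSR	semaphorin_plexin	SEMA + PSI	c126864_g2_i1_1-2228	Plexin-B	1.33	0.39	0.72
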