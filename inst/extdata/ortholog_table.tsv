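rat_gene	rat_chrom	rat_start	rat_end	human_gene	human_chrom	human_start	human_end	pct_id_target	pct_id_query	goc_score	wga_coverage	confidence
Adora2a	20	16449385	16466147	ADORA2A	22	24813847	24838328	82	82	100	87.44	1
Bcl3	1	81996116	82010351	BCL3	19	45250962	45263301	82	83	100	59.56	1
Ccl22	19	10668403	10675173	CCL22	16	57392684	57400102	65	65	100	53.85	1
Ccr1	8	132147929	132153481	CCR1	3	46243200	46249887	80	80	75	100	1
Cd14	18	29265353	29266946	CD14	5	140011313	140013286	62	63	75	100	1
Cd44	3	99339455	99426032	CD44	11	35160417	35253949	71	68	100	91.02	1
Csf2rb	7	119544873	119558539	CSF2RB	22	37309670	37336491	56	56	100	100	1
Emp1	4	233415324	233449254	EMP1	12	13349650	13369708	76	74	75	100	1
Fosl1	1	227755887	227764393	FOSL1	11	65659520	65668044	92	91	100	100	1
Glycam1	7	142951738	142953998	*
Gpr6	20	47518790	47521561	GPR6	6	110299514	110301921	94	94	50	99.76	1
Gpr88	2	237334865	237339419	GPR88	1	101003693	101007574	95	95	50	100	1
Hmox1	19	25622556	25629372	HMOX1	22	35776354	35790207	80	80	50	100	1
Il6	4	3095536	3100112	IL6	7	22765503	22771621	40	40	0	100	0
Lcn2	3	16763059	16766466	LCN2	9	130911350	130915734	64	64	100	100	1
Lgals3	15	28094062	28106276	LGALS3	14	55590828	55612126	82	78	100	96.41	1
Mcm5	19	25637492	25681915	MCM5	22	35796056	35821423	47	97	50	99.53	0
Olr1	4	211883405	211905489	OLR1	12	10310902	10324737	66	49	75	100	0
Osmr	2	75851664	75892056	OSMR	5	38845960	38945698	56	57	100	99.6	1
Ptx3	2	177457263	177463073	PTX3	3	157154578	157161417	81	81	100	100	1
Rgs9	10	97225541	97298645	RGS9	17	63133549	63223821	91	90	75	67.67	1
Sdc1	6	43667444	43689898	SDC1	2	20400558	20425194	77	76	100	100	1
Serpine1	12	24653385	24663763	SERPINE1	7	100770370	100782547	81	81	100	100	1
Spp1	14	6653093	6658953	SPP1	4	88896819	88904562	63	62	100	66.28	1
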