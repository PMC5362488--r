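protein	entry_name	estimate	cv_sr	cv_tr	where_significant	biomarker_or_drug_target	secreted	exosome	database_match	published_score
P14174	MIF_HUMAN	-1.092	3.7	23.2	Hof 8 Hour	1	0	1	1	4
Q969N2-5	PIGT_HUMAN	1.317	5.6	24.7	Hof 8 Hour	1	1	1	0	3
P04075	ALDOA_HUMAN	-1.600	1.4	2.1	Abl 24 Hour	0	1	1	0	3
P05114	HMGN1_HUMAN	-1.069	20.3	33.1	Abl 8 Hour	1	0	1	1	3
Q14573	ITPR3_HUMAN	-0.966	5.0	4.5	Hof 24 Hour	0	0	1	1	3
O00468-6	AGRIN_HUMAN	1.099	10.7	1.0	Abl 24 Hour	0	1	1	0	2
Q9H488	OFUT1_HUMAN	-1.501	14.9	2.2	Abl 24 Hour	0	1	1	0	2
O43291	SPIT2_HUMAN	1.698	4.0	7.3	Abl 24 Hour	0	1	1	0	2
Q02809	PLOD1_HUMAN	-1.834	6.5	7.6	Abl 24 Hour	0	1	1	0	2
Q10471	GALT2_HUMAN	0.604	13.0	8.3	Hof 8 Hour	0	1	1	0	2
Q7L5N1	CSN6_HUMAN	-1.710	11.3	9.8	Hof 8 Hour	0	1	1	0	2
P13987	CD59_HUMAN	1.554	8.5	10.0	LNCaP 24 Hour	0	1	1	0	2
Q03252	LMNB2_HUMAN	-0.852	1.1	10.0	Hof 8 Hour	0	1	1	0	2
Q5T653	RM02_HUMAN	-2.183	9.0	11.0	LNCaP 8 Hour	0	1	1	0	2
Q969H8	CS010_HUMAN	-1.019	3.0	11.0	Hof 8 Hour	0	1	1	0	2
P43304	GPDM_HUMAN	0.202	28.3	15.9	Abl 8 Hour	0	1	1	0	2
P14314-2	GLU2B_HUMAN	-1.481	2.8	18.4	Hof 8 Hour	0	1	1	0	2
Q7Z7H5	TMED4_HUMAN	0.596	11.5	19.3	Hof 8 Hour	0	1	1	0	2
A0AVT1	UBA6_HUMAN	-1.182	14.9	1.9	Abl 24 Hour	1	0	1	0	2
Q7KZF4	SND1_HUMAN	1.398	2.2	4.1	LNCaP 24 Hour	1	0	1	0	2
Q12792	TWF1_HUMAN	-0.939	21.0	5.8	Abl 24 Hour	1	0	1	0	2
P12277	KCRB_HUMAN	-0.991	14.3	7.3	Abl 24 Hour	1	0	1	0	2
P02144	MYG_HUMAN	-1.494	12.8	7.6	LNCaP 8 Hour	1	0	1	0	2
P13861	KAP2_HUMAN	-1.741	8.6	10.8	Hof 24 Hour	1	0	1	0	2
Q9NP58-4	ABCB6_HUMAN	0.553	8.6	6.9	Hof 24 Hour	1	0	1	0	2
P26358	DNMT1_HUMAN	1.399	18.3	7.6	Hof 24 Hour	0	0	1	1	2
Q92597	NDRG1_HUMAN	-1.885	26.9	19.3	Abl 24 Hour	0	0	1	0	2
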