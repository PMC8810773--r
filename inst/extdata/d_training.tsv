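peptide	protein	site	kcat_over_km	kcat_over_km_se	kcat_over_km_bound	kcat	kcat_se	kcat_bound	km	km_se	km_bound	score	note
EGkFVR	LMNA	450	220000	40000	exact	4.2	0.7	exact	19	4	exact	-1123	template peptide
SDkTIG	TUBA1A; TUBA4A; TUBA3E; TUBA1C; TUBA1B	40	70000	30000	exact	2.1	0.3	exact	29	15	exact	-1111	
AMkHRS	MYO1G	90	63000	9000	exact	1.9	0.2	exact	30	7	exact	-1114	
LAkEMK	CFAP157	35	60000	20000	exact	1.4	0.2	exact	20	10	exact	-1120	
TGkTVA	COF1	146	50000	10000	exact	1.37	0.09	exact	27	7	exact	-1120	
RTkSGD	ARHGEF1	234	47000	9000	exact	1.5	0.2	exact	32	9	exact	-1127	
SQkKTF	GRP94	682	44000	9000	exact	1.6	0.1	exact	36	10	exact	-1103	
AGkRIA	DIP2A	962	40000	10000	exact	1.9	0.5	exact	50	30	exact	-1110	
YKkFYE	HSP90A	436	40000	10000	exact	1.8	0.6	exact	21	9	exact	-1114	printed kcat/KM inconsistent with printed kcat and KM
YGkLRK	ACTN1	195	31000	4000	exact	6.0	0.7	exact	200	80	exact	-1115	
EGkTNY	ZNF587	209	29000	7000	exact	2.0	0.4	exact	70	30	exact	-1110	
QKkVKE	ZNF280D	32	28000	6000	exact	1.8	0.2	exact	60	20	exact	-1116	
YEkEKE	KIF5A; KIF5C; KIF5B	348	27000	5000	exact	1.8	0.1	exact	60	10	exact	-1106	
EGkTGE	ZKSCAN1	310	25000	4000	exact	1.07	0.08	exact	43	9	exact	-1112	
LSkKSK	PARP1	505	24000	3000	exact	1.7	0.2	exact	70	20	exact	-1105	
PAkESP	ATBF1; treacle	3416	22000	4000	exact	1.08	0.05	exact	49	9	exact	-1112	
AMkKIR	CDK1	33	16000	2000	exact	0.98	0.09	exact	60	10	exact	-1102	
QYkKEL	LMNA	260	13200	700	exact	1.58	0.08	exact	120	10	exact	-1106	
KTkPIW	HSP90A	294	12000	2000	exact	0.8	0.1	exact	60	20	exact	-1082	
AHkRGS	DPP3; CBLL2; RFPL4A	294	9000	3000	exact	1	NA	lower	150	NA	lower	-1117	
KLkKKE	MYH1	1085	5700	1100	exact	0.50	0.09	exact	90	30	exact	-1105	
EVkKMT	MAP4	847	5600	800	exact	0.19	0.02	exact	35	7	exact	-1105	
GYkKTK	RPL4	162	5000	2000	exact	2.3	0.5	exact	400	200	exact	-1103	
AHkKSH	S100A8	84	4700	400	exact	0.5	NA	lower	100	NA	lower	-1099	
PLkKDR	RPL3	393	2100	200	exact	0.5	NA	lower	200	NA	lower	-1100	
SWkDGL	ACTN2	181	1200	300	exact	0.3	NA	lower	200	NA	lower	-1094	
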