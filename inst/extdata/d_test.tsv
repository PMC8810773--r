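peptide	protein	site	kcat_over_km	kcat_over_km_se	kcat_over_km_bound	kcat	kcat_se	kcat_bound	km	km_se	km_bound	score	note
FPkEAK	EGFR	1179	40000	5000	exact	0.53	0.02	exact	13	2	exact	-1120	
HSkGFG	TARDBP	145	40000	10000	exact	1.2	0.3	exact	30	20	exact	-1122	
QAkSPP	MEF2C	239	26000	4000	exact	1.2	0.2	exact	40	10	exact	-1125	
ISkMND	IFI16	451	25000	9000	exact	0.48	0.08	exact	20	10	exact	-1114	
SGkGKK	GATA1	312	16000	3000	exact	0.31	0.03	exact	19	6	exact	-1131	
PGkEEK	FOXM1	440	15000	4000	exact	0.5	0.1	exact	35	16	exact	-1117	
KGkQAE	HMGN1	61	14000	3000	exact	0.36	0.04	exact	26	8	exact	-1122	
NGkLTG	GAPDH	227	14000	1000	exact	0.36	0.03	exact	26	4	exact	-1111	
MGkGVS	ENO1	60	11000	1000	exact	0.49	0.06	exact	40	10	exact	-1119	
PCkEVD	NFAT5	282	4800	500	exact	0.2	NA	lower	20	NA	lower	-1107	
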