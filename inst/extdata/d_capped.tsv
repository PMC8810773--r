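peptide	protein	site	kcat_over_km	kcat_over_km_se	kcat_over_km_bound	kcat	kcat_se	kcat_bound	km	km_se	km_bound	score	note
YDkDEV	SIRT1	430	110000	NA	lower	0.28	0.04	exact	25	NA	upper	-1103	
MEkFKI	XPOT	627	80000	NA	lower	2.0	0.5	exact	25	NA	upper	-1115	
ETkYRW	VDAC1	61	70000	NA	lower	3.7	1.2	exact	50	NA	upper	-1123	
GGkRVM	VPS35	694	60000	NA	lower	1.4	0.2	exact	25	NA	upper	-1116	
YDkLRK	ACTN4; TUBG1	214	50000	NA	lower	1.2	0.2	exact	25	NA	upper	-1110	
HGkEVG	PCPB1	23	40000	NA	lower	2.2	0.5	exact	50	NA	upper	-1111	
QGkSGN	MYO18B	401	40000	NA	lower	1.1	0.2	exact	25	NA	upper	-1113	
IDkRTI	EEF1A1; EEF1A2; EEF1A1P5	31	40000	NA	lower	1.0	0.2	exact	25	NA	upper	-1104	
GAkDEP	COF1	1414	40000	NA	lower	0.9	0.2	exact	25	NA	upper	-1109	seventh residue merged with protein name in source table; truncated to core hexamer
VSkRKL	UBA1; ARHGAP32	1024	40000	NA	lower	1.0	0.1	exact	25	NA	upper	-1103	
YEkFRN	USP32	145	40000	NA	lower	1.1	0.2	exact	25	NA	upper	-1117	
MKkLKE	PASD1	379	30000	NA	lower	0.7	0.1	exact	25	NA	upper	-1118	
SQkYKR	MART3	473	30000	NA	lower	1.3	0.4	exact	50	NA	upper	-1124	calculated from 3 data points
CGkGLE	CSRP1	151	20000	NA	lower	1.1	0.4	exact	50	NA	upper	-1124	
SEkILQ	COF1	294	20000	NA	lower	1.2	0.2	exact	50	NA	upper	-1103	seventh residue merged with protein name in source table; truncated to core hexamer
EGkGNG	EIF5	28	17000	NA	lower	0.84	0.09	exact	50	NA	upper	-1122	
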