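study	stage	n_highrisk	n_controls	n_riskmatched	n_cases
ADC1	discovery	52	512	842	1524
ADC2	discovery	16	155	386	620
ADC3	discovery	57	566	379	666
ADC4	discovery	38	376	222	304
ADC5	discovery	51	503	187	285
ADC6	discovery	34	337	68	213
MAYO	discovery	112	1117	626	754
UM/VU/MSSM	discovery	113	1108	753	1123
ACT+GenDiff	discovery	157	1556	425	524
MIRAGE	discovery	51	509	101	137
WASHU1	discovery	18	176	137	253
ROSMAP	discovery	72	717	192	237
UPITT	discovery	82	811	794	1152
OHSU	discovery	18	180	119	174
Tgen II	discovery	36	360	364	613
NIA-LOAD	discovery	102	1007	582	760
ROSMAP2	discovery	22	214	50	59
WASHU2	discovery	8	71	29	36
MTC	discovery	19	188	220	252
TARCC	discovery	18	176	241	306
WHICAP	discovery	56	553	17	72
ADNI-1	discovery	13	127	174	350
CHS	discovery	168	1661	274	451
FHS	discovery	191	1901	137	288
EADI	discovery	620	6172	1636	2167
GERAD	discovery	139	1388	2354	2992
AddNeuroMed	replication	19	183	38	223
ADC7	replication	79	784	45	513
ADNI-GO/2/3	replication	38	374	37	211
Norwegian DemGene	replication	75	741	163	1085
GENDER/SATSA/HARMONY	replication	77	764	39	306
TwinGene	replication	608	6080	30	287
AIBL	replication	77	762	13	111
Sydney MAS	replication	83	830	16	95
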