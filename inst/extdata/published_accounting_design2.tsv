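study	stage	n_highrisk	n_controls	n_riskmatched	n_cases
ADC1	discovery	30	150	773	1021
ADC2	discovery	9	41	212	353
ADC3	discovery	27	132	357	391
ADC4	discovery	20	100	115	160
ADC5	discovery	24	119	147	178
ADC6	discovery	19	93	94	121
MAYO	discovery	63	313	436	492
UM/VU/MSSM	discovery	51	251	430	661
ACT+GenDiff	discovery	63	314	198	234
MIRAGE	discovery	38	190	68	78
WASHU1	discovery	10	48	65	141
ROSMAP	discovery	23	114	18	87
UPITT	discovery	32	158	545	664
OHSU	discovery	5	25	49	73
Tgen II	discovery	16	76	251	396
NIA-LOAD	discovery	58	289	463	571
ROSMAP2	discovery	3	15	0	18
WASHU2	discovery	4	16	16	19
MTC	discovery	5	22	48	143
TARCC	discovery	10	47	122	184
WHICAP	discovery	23	113	8	16
ADNI-1	discovery	6	28	97	230
CHS	discovery	66	330	99	148
FHS	discovery	74	370	54	94
EADI	discovery	247	1235	870	1072
GERAD	discovery	62	310	1006	1623
AddNeuroMed	replication	9	44	19	121
ADC7	replication	51	252	57	320
ADNI-GO/2/3	replication	23	113	38	142
Norwegian DemGene	replication	34	168	130	671
GENDER/SATSA/HARMONY	replication	40	196	34	148
TwinGene	replication	353	1765	31	156
AIBL	replication	36	180	12	71
Sydney MAS	replication	37	182	10	31
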