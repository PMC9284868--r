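matcher	pair	scope	n_inconsistent	n_inconsistent_fp	pct_printed	pct_fp_printed
AML	ORDO-SNOMEDCT	whole	494	318	8	5
FCA-Map	ORDO-SNOMEDCT	whole	489	310	10	6
LogMap	ORDO-SNOMEDCT	whole	193	106	3	2
AML	NCIT-SNOMEDCT	whole	3055	252	16	1
FCA-Map	NCIT-SNOMEDCT	whole	6868	3299	26	12
LogMap	NCIT-SNOMEDCT	whole	3790	1180	16	5
AML	NCIT-ORDO	whole	127	102	5	4
FCA-Map	NCIT-ORDO	whole	1229	1170	3	3
LogMap	NCIT-ORDO	whole	130	92	5	3
AML	ORDO-SNOMEDCT	module	9	6	21	14
FCA-Map	ORDO-SNOMEDCT	module	11	8	24	17
LogMap	ORDO-SNOMEDCT	module	5	3	9	6
AML	NCIT-SNOMEDCT	module	46	13	24	7
FCA-Map	NCIT-SNOMEDCT	module	60	23	27	10
LogMap	NCIT-SNOMEDCT	module	42	9	20	4
AML	NCIT-ORDO	module	4	1	11	3
FCA-Map	NCIT-ORDO	module	12	8	26	17
LogMap	NCIT-ORDO	module	3	0	10	0
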