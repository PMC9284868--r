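matcher	pair	n_whole	n_module
AML	ORDO-SNOMEDCT	6463	42
AML	NCIT-ORDO	2543	36
AML	NCIT-SNOMEDCT	18887	193
FCA-Map	ORDO-SNOMEDCT	4973	46
FCA-Map	NCIT-ORDO	4663	47
FCA-Map	NCIT-SNOMEDCT	26630	220
LogMap	ORDO-SNOMEDCT	5742	53
LogMap	NCIT-ORDO	2679	31
LogMap	NCIT-SNOMEDCT	23885	214
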