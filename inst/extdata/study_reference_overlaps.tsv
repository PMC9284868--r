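pair	scope	n_umls	n_bioportal	n_overlap
ORDO-SNOMEDCT	module	35	7	3
NCIT-ORDO	module	27	18	12
NCIT-SNOMEDCT	module	127	90	56
ORDO-SNOMEDCT	whole	3861	1750	776
NCIT-ORDO	whole	1484	1450	656
NCIT-SNOMEDCT	whole	19309	16290	10195
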