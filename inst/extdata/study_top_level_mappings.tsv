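pair	iri_a	label_a	iri_b	label_b
ORDO-SNOMEDCT	Orphanet_C001	clinical entity	404684003	Clinical finding
ORDO-SNOMEDCT	Orphanet_C010	genetic material	105590001	Substance
ORDO-SNOMEDCT	Orphanet_C009	geography	308916002	Environment or geographical location
NCIT-ORDO	C7057	Disease, Disorder or Finding	Orphanet_C001	clinical entity
NCIT-ORDO	C26548	Gene Product	Orphanet_C010	genetic material
NCIT-ORDO	C20181	Conceptual Entity	Orphanet_C009	geography
NCIT-ORDO	C20181	Conceptual Entity	Orphanet_C005	inheritance
NCIT-ORDO	C20189	Property or Attribute	Orphanet_C023	age of onset
NCIT-SNOMEDCT	C12219	Anatomic Structure, System, or Substance	123037004	Body structure
NCIT-SNOMEDCT	C7057	Disease, Disorder or Finding	404684003	Clinical finding
NCIT-SNOMEDCT	C20189	Property or Attribute	362981000	Qualifier value
NCIT-SNOMEDCT	C12219	Anatomic Structure, System, or Substance	105590001	Substance
NCIT-SNOMEDCT	C43431	Activity	71388002	Procedure
NCIT-SNOMEDCT	C14250	Organism	410607006	Organism
NCIT-SNOMEDCT	C1908	Drug, Food, Chemical or Biomedical Material	105590001	Substance
NCIT-SNOMEDCT	C1908	Drug, Food, Chemical or Biomedical Material	373873005	Pharmaceutical / biologic product
NCIT-SNOMEDCT	C97325	Manufactured Object	260787004	Physical object
NCIT-SNOMEDCT	C20189	Property or Attribute	363787002	Observable entity
NCIT-SNOMEDCT	C20181	Conceptual Entity	308916002	Environment or geographical location
NCIT-SNOMEDCT	C20181	Conceptual Entity	48176007	Social context
NCIT-SNOMEDCT	C20181	Conceptual Entity	363787002	Observable entity
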