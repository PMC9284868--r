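Package: ontalign
Title: Evaluation of Biomedical Ontology Alignments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the quality of alignments between biomedical
    ontologies such as SNOMED CT, the NCI Thesaurus, and the Orphanet Rare
    Disease Ontology. Provides a lightweight rooted-DAG ontology model with
    readers for an RDF/XML OWL dialect and a TSV hierarchy format,
    seed-signature module extraction (top/bottom/star), Alignment API RDF
    input and output, construction of reference alignments from shared UMLS
    Concept Unique Identifiers (CUIs), precision/recall/F-measure scoring
    against possibly incomplete references, a top-level-hierarchy consistency
    filter that flags mappings whose classes descend from unmatched top-level
    categories, vote-based consensus alignments across matchers, and a
    synthetic ontology-pair generator with planted correct and incorrect
    mappings for end-to-end validation without licensed terminologies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
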