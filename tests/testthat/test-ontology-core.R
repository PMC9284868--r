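test_that("ontology construction validates its invariants", {
  expect_s3_class(chain_ontology(), "ontology")
  # duplicate iri
  expect_error(
    ontology("X", c("r", "a", "a"),
             list(r = character(), a = "r", a = "r")),
    "duplicate")
  # two-node cycle is rejected
  expect_error(
    ontology("X", c("root", "A", "B"),
             list(root = character(), A = c("B", "root"), B = c("A", "root"))),
    "cycle")
  # several parentless classes
  expect_error(
    ontology("X", c("r1", "r2"), list(r1 = character(), r2 = character())),
    "parentless|root")
  # self-parent
  expect_error(
    ontology("X", c("r", "a"), list(r = character(), a = c("a", "r"))),
    "own parent")
})

test_that("ancestors and descendants follow all paths in chains and diamonds", {
  ch <- chain_ontology()
  expect_setequal(ancestors(ch, "c"), c("b", "a", "root"))
  expect_setequal(ancestors(ch, "root"), character(0))
  expect_setequal(descendants(ch, "root"), c("a", "b", "c"))
  expect_setequal(descendants(ch, "c"), character(0))

  di <- diamond_ontology()
  expect_setequal(ancestors(di, "d"), c("b", "c", "a", "root"))
  expect_setequal(descendants(di, "a"), c("b", "c", "d"))

  expect_error(ancestors(ch, "zz"), "unknown class iri")
  expect_error(descendants(ch, "zz"), "unknown class iri")
})

test_that("ancestors/descendants agree with a brute-force reachability oracle", {
  set.seed(101)
  for (rep in 1:15) {
    ont <- random_dag_ontology(sample(5:50, 1))
    reach <- reachability_oracle(ont)
    for (iri in ont$iris) {
      expect_setequal(ancestors(ont, iri), oracle_ancestors(reach, iri))
      expect_setequal(descendants(ont, iri), oracle_descendants(reach, iri))
    }
    # mutual consistency: b ancestor of a <=> a descendant of b
    for (iri in sample(ont$iris, min(5, length(ont$iris)))) {
      for (anc in ancestors(ont, iri)) {
        expect_true(iri %in% descendants(ont, anc))
      }
    }
  }
})

test_that("top-level classes and top-level ancestors behave as categories", {
  di <- diamond_ontology()
  expect_setequal(top_level_classes(di), "a")
  expect_setequal(top_level_ancestors(di, "d"), "a")
  # a top-level class is its own top-level ancestor
  expect_setequal(top_level_ancestors(di, "a"), "a")
  expect_error(top_level_ancestors(di, "root"), "root")

  # class under two distinct top-level classes reports both
  multi <- make_ont(list(t1 = "root", t2 = "root", x = c("t1", "t2")))
  expect_setequal(top_level_ancestors(multi, "x"), c("t1", "t2"))

  # root-only ontology has no top-level classes
  solo <- ontology("S", "root", list(root = character()))
  expect_length(top_level_classes(solo), 0)

  # every non-root class of a random DAG has at least one top-level ancestor
  set.seed(33)
  ont <- random_dag_ontology(40)
  tls <- top_level_classes(ont)
  for (iri in setdiff(ont$iris, ont$root_iri)) {
    tla <- top_level_ancestors(ont, iri)
    expect_gte(length(tla), 1)
    expect_true(all(tla %in% tls))
  }
})

test_that("a 19-category synthetic ontology has 19 top-level classes", {
  sc <- generate_scenario(synthetic_config(
    seed = 5, n_categories_a = 19, n_categories_b = 19,
    classes_per_category = 3))
  expect_length(top_level_classes(sc$ontology_a), 19)
  expect_length(top_level_classes(sc$ontology_b), 19)
})

test_that("TSV loader validates and round-trips", {
  dir <- withr::local_tempdir()
  ont <- diamond_ontology()
  ont$labels["d"] <- "deep class"
  ont$cuis[["d"]] <- c("C0032461", "C0000001")
  ont$synonyms[["d"]] <- "deep synonym"
  f <- file.path(dir, "toy.tsv")
  write_ontology_tsv(ont, f)
  back <- load_ontology_tsv(f, "T")
  expect_setequal(back$iris, ont$iris)
  expect_identical(lapply(back$parents[sort(back$iris)], sort),
                   lapply(ont$parents[sort(ont$iris)], sort))
  expect_identical(back$cuis[["d"]], sort(ont$cuis[["d"]]))
  # second write reproduces the file byte for byte
  f2 <- file.path(dir, "toy2.tsv")
  write_ontology_tsv(back, f2)
  expect_identical(readLines(f), readLines(f2))

  # single-row file: root only
  writeLines(c("iri\tparent_iris\tlabel\tsynonyms\tcuis",
               "r\t\tRoot\t\t"), file.path(dir, "solo.tsv"))
  expect_length(load_ontology_tsv(file.path(dir, "solo.tsv"))$iris, 1)

  # two parentless rows
  writeLines(c("iri\tparent_iris\tlabel\tsynonyms\tcuis",
               "r1\t\tA\t\t", "r2\t\tB\t\t"),
             file.path(dir, "tworoots.tsv"))
  expect_error(load_ontology_tsv(file.path(dir, "tworoots.tsv")),
               "parentless")
  # duplicate iri
  writeLines(c("iri\tparent_iris\tlabel\tsynonyms\tcuis",
               "r\t\tA\t\t", "x\tr\tB\t\t", "x\tr\tC\t\t"),
             file.path(dir, "dup.tsv"))
  expect_error(load_ontology_tsv(file.path(dir, "dup.tsv")), "duplicate")
})

test_that("OWL loader parses hierarchy, labels, CUIs, and rejects cycles", {
  dir <- withr::local_tempdir()
  # minimal hierarchy: R with A below R and B below A
  owl <- c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '  xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
    '  xmlns:owl="http://www.w3.org/2002/07/owl#"',
    '  xmlns:umls="http://purl.bioontology.org/ontology/UMLS/">',
    '  <owl:Class rdf:about="R"><rdfs:label>Root</rdfs:label></owl:Class>',
    '  <owl:Class rdf:about="A"><rdfs:subClassOf rdf:resource="R"/></owl:Class>',
    '  <owl:Class rdf:about="X">',
    '    <umls:cui>C0032461</umls:cui>',
    '    <rdfs:subClassOf rdf:resource="A"/>',
    '  </owl:Class>',
    '</rdf:RDF>')
  f <- file.path(dir, "mini.owl")
  writeLines(owl, f)
  ont <- load_ontology_owl(f, "MINI")
  expect_length(ont$iris, 3)
  expect_identical(ont$root_iri, "R")
  expect_identical(ont$cuis[["X"]], "C0032461")
  expect_identical(unname(ont$labels["R"]), "Root")

  # A below B and B below A: smallest cycle
  cyc <- c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '  xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
    '  xmlns:owl="http://www.w3.org/2002/07/owl#">',
    '  <owl:Class rdf:about="A"><rdfs:subClassOf rdf:resource="B"/></owl:Class>',
    '  <owl:Class rdf:about="B"><rdfs:subClassOf rdf:resource="A"/></owl:Class>',
    '</rdf:RDF>')
  fc <- file.path(dir, "cycle.owl")
  writeLines(cyc, fc)
  expect_error(load_ontology_owl(fc), "cycle|root")

  # unparsable file
  fb <- file.path(dir, "broken.owl")
  writeLines("<rdf:RDF", fb)
  expect_error(suppressWarnings(load_ontology_owl(fb)),
               "cannot parse|namespace")
})

test_that("OWL and TSV loaders agree on paired synthetic fixtures", {
  sc <- small_scenario()
  dir <- withr::local_tempdir()
  fs <- write_scenario(sc, dir)
  for (side in c("a", "b")) {
    id <- if (side == "a") "ONTA" else "ONTB"
    o_tsv <- load_ontology_tsv(fs[[paste0("ontology_", side, "_tsv")]], id)
    o_owl <- load_ontology_owl(fs[[paste0("ontology_", side, "_owl")]], id)
    expect_setequal(o_tsv$iris, o_owl$iris)
    ord <- sort(o_tsv$iris)
    expect_identical(lapply(o_tsv$parents[ord], sort),
                     lapply(o_owl$parents[ord], sort))
    expect_identical(o_tsv$labels[ord], o_owl$labels[ord])
    expect_identical(lapply(o_tsv$cuis[ord], sort),
                     lapply(o_owl$cuis[ord], sort))
    expect_identical(o_tsv$root_iri, o_owl$root_iri)
  }
})
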