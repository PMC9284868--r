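# two toy ontologies with two top-level categories each; only the
# (ta1, tb1) categories are manually matched
toy_pair <- function() {
  onta <- make_ont(list(ta1 = "root", ta2 = "root",
                        a1 = "ta1", a2 = "a1", a3 = "ta2"), id = "A")
  ontb <- make_ont(list(tb1 = "root", tb2 = "root",
                        b1 = "tb1", b2 = "b1", b3 = "tb2"), id = "B")
  tlms <- top_level_mapping_set(c("A", "B"),
                                data.frame(iri_a = "ta1", iri_b = "tb1"),
                                onto_a = onta, onto_b = ontb)
  list(a = onta, b = ontb, tlms = tlms)
}

test_that("curated top-level mapping tables load and validate per pair", {
  path <- system.file("extdata", "study_top_level_mappings.tsv",
                      package = "ontalign")
  ncit_sct <- load_top_level_mappings(path, pair = "NCIT-SNOMEDCT")
  expect_identical(nrow(ncit_sct$pairs), 13L)
  ordo_sct <- load_top_level_mappings(path, pair = "ORDO-SNOMEDCT")
  expect_identical(nrow(ordo_sct$pairs), 3L)
  # many-to-many is preserved: one NCIt top maps to several SNOMED tops
  expect_gte(sum(ncit_sct$pairs$iri_a == "C20181"), 3)

  # a row pairing a non-top-level (leaf) class is rejected by row number
  toy <- toy_pair()
  expect_error(
    top_level_mapping_set(c("A", "B"),
                          data.frame(iri_a = c("ta1", "a2"),
                                     iri_b = c("tb1", "tb1")),
                          onto_a = toy$a, onto_b = toy$b),
    "row 2")
})

test_that("hierarchy consistency is an existential check over matched categories", {
  toy <- toy_pair()
  # both classes under the matched category pair
  expect_true(mapping_hierarchy_consistent("a2", "b2", toy$a, toy$b,
                                           toy$tlms))
  # classes under categories that were never manually matched
  expect_false(mapping_hierarchy_consistent("a3", "b3", toy$a, toy$b,
                                            toy$tlms))
  expect_false(mapping_hierarchy_consistent("a2", "b3", toy$a, toy$b,
                                            toy$tlms))
  # a mapping between the matched top-level classes themselves
  expect_true(mapping_hierarchy_consistent("ta1", "tb1", toy$a, toy$b,
                                           toy$tlms))
  # multi-inheritance: any one matching ancestor pair suffices
  multi_a <- make_ont(list(ta1 = "root", ta2 = "root",
                           x = c("ta1", "ta2")), id = "A")
  expect_true(mapping_hierarchy_consistent("x", "b2", multi_a, toy$b,
                                           toy$tlms))
  expect_error(mapping_hierarchy_consistent("nope", "b1", toy$a, toy$b,
                                            toy$tlms), "unknown")
})

test_that("alignment analysis counts inconsistent mappings and candidate FPs", {
  toy <- toy_pair()
  al <- alignment("A", "B", rbind(
    mappings(c("a1", "a2"), c("b1", "b2")),   # consistent
    mappings(c("a3", "a1", "a2", "ta2"),
             c("b3", "b3", "b3", "tb2"))))    # 4 inconsistent
  # one inconsistent mapping is protected as a TP of some reference
  tp_union <- data.frame(source_iri = "a3", target_iri = "b3")
  res <- analyze_alignment(al, toy$a, toy$b, toy$tlms, tp_union = tp_union)
  expect_identical(res$inconsistent_count, 4L)
  expect_identical(res$inconsistent_fp_count, 3L)
  expect_equal(res$proportion_inconsistent, 4 / 6)
  expect_equal(res$proportion_inconsistent_fp, 3 / 6)
  expect_identical(nrow(res$consistent) + nrow(res$inconsistent) +
                     nrow(res$unresolvable), nrow(al$mappings))

  # all consistent
  ok <- analyze_alignment(alignment("A", "B", mappings("a1", "b1")),
                          toy$a, toy$b, toy$tlms)
  expect_identical(ok$inconsistent_count, 0L)

  # empty alignment: proportions are undefined markers
  none <- analyze_alignment(alignment("A", "B"), toy$a, toy$b, toy$tlms)
  expect_true(is.na(none$proportion_inconsistent))

  # unknown classes land in the unresolvable bucket
  ghost <- analyze_alignment(
    alignment("A", "B", mappings(c("a1", "zz"), c("b1", "b1"))),
    toy$a, toy$b, toy$tlms)
  expect_identical(ghost$unresolvable_count, 1L)
  expect_identical(ghost$inconsistent_count, 0L)
})

test_that("published alignment sizes and inconsistency counts reproduce printed proportions", {
  counts <- study_table("hierarchy_counts")
  sizes <- study_table("alignment_sizes")
  aml_osct <- counts[counts$matcher == "AML" &
                       counts$pair == "ORDO-SNOMEDCT" &
                       counts$scope == "whole", ]
  n <- sizes$n_whole[sizes$matcher == "AML" & sizes$pair == "ORDO-SNOMEDCT"]
  expect_identical(format_percent(100 * aml_osct$n_inconsistent / n), "8%")
  expect_identical(format_percent(100 * aml_osct$n_inconsistent_fp / n), "5%")
})

test_that("the filter removes only inconsistent non-TP mappings and re-scores", {
  toy <- toy_pair()
  # 10 mappings: 5 TP of the reference, 5 FP of which 2 are inconsistent
  al <- alignment("A", "B", rbind(
    mappings(c("a1", "a2", "ta1", "a1", "a2"),
             c("b1", "b2", "tb1", "b2", "b1")),      # 5 consistent (TP)
    mappings(c("a1", "a2", "ta1"), c("tb1", "tb1", "b1")),  # consistent FPs
    mappings(c("a3", "ta2"), c("b3", "tb2"))))       # inconsistent FPs
  ref <- alignment("A", "B", mappings(
    c("a1", "a2", "ta1", "a1", "a2"), c("b1", "b2", "tb1", "b2", "b1")))
  analysis <- analyze_alignment(al, toy$a, toy$b, toy$tlms)
  expect_identical(analysis$inconsistent_count, 2L)
  rr <- filter_and_reevaluate(al, analysis, list(reference = ref))
  before <- rr$scores$reference$before
  after <- rr$scores$reference$after
  expect_equal(before$precision, 0.5)
  expect_equal(after$precision, 5 / 8)
  expect_equal(before$recall, after$recall)
  expect_identical(nrow(rr$removed), 2L)

  # an inconsistent mapping that is TP of one reference is retained
  ref2 <- alignment("A", "B", mappings("a3", "b3"))
  rr2 <- filter_and_reevaluate(al, analysis, list(r1 = ref, r2 = ref2))
  expect_false("a3" %in% rr2$removed$source_iri)
  expect_true("ta2" %in% rr2$removed$source_iri)

  # no inconsistent mappings: scores unchanged
  clean <- alignment("A", "B", mappings(c("a1", "a2"), c("b1", "b2")))
  an_clean <- analyze_alignment(clean, toy$a, toy$b, toy$tlms)
  rr3 <- filter_and_reevaluate(clean, an_clean, list(reference = ref))
  expect_equal(rr3$scores$reference$before$precision,
               rr3$scores$reference$after$precision)
  expect_error(filter_and_reevaluate(al, analysis, list()), "at least one")
})

test_that("filtering never changes recall and never lowers precision", {
  set.seed(61)
  for (rep in 1:8) {
    sc <- small_scenario(seed = rep)
    pair <- c("ONTA", "ONTB")
    al <- normalize_alignment(
      simulate_matcher(sc, seed = 1000 + rep), pair)
    refs <- list(
      silver = normalize_alignment(
        build_cui_reference(sc$cui_a, sc$cui_b), pair),
      base = normalize_alignment(
        degrade_reference(sc$ground_truth, 0.5, seed = rep), pair))
    keys <- paste(al$mappings$source_iri, al$mappings$target_iri)
    tp_keys <- unique(unlist(lapply(refs, function(r)
      intersect(keys, paste(r$mappings$source_iri,
                            r$mappings$target_iri)))))
    tp_union <- al$mappings[keys %in% tp_keys, ]
    analysis <- analyze_alignment(al, sc$ontology_a, sc$ontology_b,
                                  sc$top_level_mappings,
                                  tp_union = tp_union)
    rr <- filter_and_reevaluate(al, analysis, refs)
    for (s in rr$scores) {
      expect_identical(s$before$recall, s$after$recall)
      if (!is.na(s$before$precision) && !is.na(s$after$precision)) {
        expect_gte(s$after$precision, s$before$precision)
      }
      expect_identical(s$before$tp, s$after$tp)
    }
  }
})

test_that("on synthetic data the filter flags exactly the planted cross-category FPs", {
  sc <- small_scenario(seed = 99)
  al <- normalize_alignment(simulate_matcher(sc, seed = 7),
                            c("ONTA", "ONTB"))
  analysis <- analyze_alignment(al, sc$ontology_a, sc$ontology_b,
                                sc$top_level_mappings)
  flagged <- paste(analysis$inconsistent$source_iri,
                   analysis$inconsistent$target_iri)
  planted_cross <- with(al$mappings, paste(source_iri, target_iri)[
    planted == "false_cross_category"])
  expect_setequal(flagged, planted_cross)
  # gamma = 0.5 of 20 planted false mappings, applied as an exact count
  expect_identical(length(planted_cross), 10L)
})
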