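test_that("CUI tables validate codes and round-trip through TSV", {
  expect_error(cui_table("A", list(x = "12345")), "invalid CUI")
  tab <- cui_table("A", list(x = c("C1", "C2"), y = character(0)))
  expect_setequal(names(tab$cui_map), "x")  # empty entries dropped
  dir <- withr::local_tempdir()
  f <- file.path(dir, "cui.tsv")
  write_cui_table(tab, f)
  back <- read_cui_table(f, "A")
  expect_identical(back$cui_map, list(x = c("C1", "C2")))
})

test_that("CUI-based reference contains exactly the shared-CUI class pairs", {
  ref <- build_cui_reference(cui_table("A", list(a = "C1")),
                             cui_table("B", list(b = c("C1", "C2"))))
  expect_identical(nrow(ref$mappings), 1L)
  expect_identical(ref$mappings$source_iri, "a")
  expect_identical(ref$mappings$relation, "equivalence")
  expect_identical(ref$mappings$confidence, 1)

  # disjoint CUI sets give an empty reference
  empty <- build_cui_reference(cui_table("A", list(a = "C1")),
                               cui_table("B", list(b = "C2")))
  expect_identical(nrow(empty$mappings), 0L)

  # shared CUI held by two classes on one side: cross product
  multi <- build_cui_reference(
    cui_table("A", list(a1 = "C1", a2 = "C1")),
    cui_table("B", list(b1 = "C1")))
  expect_setequal(mapping_keys(multi),
                  c("a1\rb1", "a2\rb1"))
  expect_error(build_cui_reference(cui_table("A", list(a = "C1")),
                                   cui_table("A", list(b = "C1"))),
               "distinct")

  # brute-force oracle on random CUI tables
  set.seed(21)
  for (rep in 1:5) {
    ta <- cui_table("A", lapply(stats::setNames(
      seq_len(12), sprintf("a%02d", 1:12)),
      function(i) sprintf("C%d", sample.int(8, sample(0:3, 1)))))
    tb <- cui_table("B", lapply(stats::setNames(
      seq_len(12), sprintf("b%02d", 1:12)),
      function(i) sprintf("C%d", sample.int(8, sample(0:3, 1)))))
    expected <- character(0)
    for (a in names(ta$cui_map)) for (b in names(tb$cui_map)) {
      if (length(intersect(ta$cui_map[[a]], tb$cui_map[[b]]))) {
        expected <- c(expected, paste(a, b, sep = "\r"))
      }
    }
    expect_setequal(mapping_keys(build_cui_reference(ta, tb)), expected)
  }
})

test_that("module restriction keeps mappings whose classes are both retained", {
  sc <- small_scenario()
  gt <- sc$ground_truth
  # whole ontologies as 'modules': unchanged
  expect_identical(
    nrow(restrict_reference_to_module(gt, sc$ontology_a,
                                      sc$ontology_b)$mappings),
    nrow(gt$mappings))
  # genuine module: kept rows are exactly those with both ends retained
  seed_a <- extend_seed_with_ancestors(
    sc$ontology_a, gt$mappings$source_iri[1:10])
  seed_b <- extend_seed_with_ancestors(
    sc$ontology_b, gt$mappings$target_iri[1:10])
  mod_a <- extract_module(sc$ontology_a, seed_a, "star")
  mod_b <- extract_module(sc$ontology_b, seed_b, "star")
  res <- restrict_reference_to_module(gt, mod_a, mod_b)
  manual <- gt$mappings$source_iri %in% mod_a$iris &
    gt$mappings$target_iri %in% mod_b$iris
  expect_identical(nrow(res$mappings), sum(manual))
  expect_error(restrict_reference_to_module(
    alignment("X", "Y", mappings("x", "y")), mod_a, mod_b),
    "does not match")
})

test_that("TP/FP/FN classification partitions A union R and matches the set oracle", {
  a <- alignment("A", "B", rbind(mappings("a1", "b1"), mappings("a2", "b2"),
                                 mappings("a3", "b3")))
  r <- alignment("A", "B", rbind(mappings("a2", "b2"), mappings("a4", "b4")))
  cl <- classify_mappings(a, r)
  expect_identical(pair_keys <- paste(cl$tp$source_iri, cl$tp$target_iri),
                   "a2 b2")
  expect_setequal(paste(cl$fp$source_iri, cl$fp$target_iri),
                  c("a1 b1", "a3 b3"))
  expect_setequal(paste(cl$fn$source_iri, cl$fn$target_iri), "a4 b4")

  # A = R: no errors; A empty: everything is a false negative
  same <- classify_mappings(a, a)
  expect_identical(nrow(same$fp), 0L)
  expect_identical(nrow(same$fn), 0L)
  none <- classify_mappings(alignment("A", "B"), r)
  expect_identical(nrow(none$tp), 0L)
  expect_identical(nrow(none$fn), nrow(r$mappings))
  expect_error(classify_mappings(a, alignment("A", "C", mappings("x", "y"))),
               "pair order")

  set.seed(31)
  for (rep in 1:25) {
    al <- random_alignment(sample(0:100, 1))
    rf <- random_alignment(sample(0:100, 1))
    cl <- classify_mappings(al, rf)
    orc <- oracle_classify(mapping_keys(al), mapping_keys(rf))
    expect_setequal(paste(cl$tp$source_iri, cl$tp$target_iri, sep = "\r"),
                    orc$tp)
    expect_setequal(paste(cl$fp$source_iri, cl$fp$target_iri, sep = "\r"),
                    orc$fp)
    expect_setequal(paste(cl$fn$source_iri, cl$fn$target_iri, sep = "\r"),
                    orc$fn)
    # partition invariants
    expect_identical(nrow(cl$tp) + nrow(cl$fp), nrow(al$mappings))
    expect_identical(nrow(cl$tp) + nrow(cl$fn), nrow(rf$mappings))
  }
})

test_that("precision, recall, and F-measure follow their definitions", {
  r <- score_counts(2, 2, 6)
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 0.25)
  expect_equal(r$f_measure, 1 / 3)
  perfect <- score_counts(1, 0, 0)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f_measure),
               c(1, 1, 1))
  worst <- score_counts(0, 5, 5)
  expect_equal(c(worst$precision, worst$recall, worst$f_measure), c(0, 0, 0))
  # undefined scores are NA markers, not zeros
  undef_p <- score_counts(0, 0, 5)
  expect_true(is.na(undef_p$precision))
  expect_true(is.na(undef_p$f_measure))
  expect_equal(undef_p$recall, 0)
  undef_r <- score_counts(0, 5, 0)
  expect_true(is.na(undef_r$recall))
  expect_error(score_counts(-1, 0, 0), "non-negative")

  # property: F lies below precision + recall and equals both when equal
  set.seed(41)
  for (rep in 1:50) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    s <- score_counts(tp, fp, fn)
    if (!is.na(s$f_measure)) {
      expect_lte(s$f_measure, min(1, s$precision + s$recall) + 1e-12)
      if (isTRUE(all.equal(s$precision, s$recall))) {
        expect_equal(s$f_measure, s$precision)
      }
    }
  }
})

test_that("overlap statistics use the weighted harmonic mean and are symmetric", {
  # published reference-alignment sizes reproduce the printed overlaps
  expect_identical(
    format_percent(100 * harmonic_overlap(3861, 1750, 776)), "28%")
  expect_identical(
    format_percent(100 * harmonic_overlap(19309, 16290, 10195)), "57%")
  expect_identical(format_percent(100 * harmonic_overlap(35, 7, 3)), "14%")
  expect_error(harmonic_overlap(5, 5, 6), "exceed")
  expect_true(is.na(harmonic_overlap(0, 0, 0)))

  set.seed(51)
  a <- random_alignment(40); b <- random_alignment(40)
  ab <- overlap_stats(a, b); ba <- overlap_stats(b, a)
  expect_equal(ab$weighted_harmonic_mean, ba$weighted_harmonic_mean)
  # identical references overlap fully
  expect_identical(overlap_stats(a, a)$pct_label, "100%")
  # harmonic mean of the two proportions equals the weighted form
  if (ab$intersection > 0) {
    hm <- 2 / (1 / ab$proportion_a + 1 / ab$proportion_b)
    expect_equal(ab$weighted_harmonic_mean, hm)
  }
})

test_that("mean aggregation averages scores and excludes undefined markers", {
  res <- list(score_counts(5, 5, 5, "u"), score_counts(3, 4, 4, "u"),
              score_counts(6, 4, 0, "b"))
  one <- aggregate_means(list(score_counts(2, 2, 6, "u")))
  expect_equal(one$precision, 0.5)
  expect_identical(one$n, 1L)

  df <- do.call(rbind, lapply(res, as.data.frame))
  by_ref <- aggregate_means(df, group_by = "reference")
  expect_equal(by_ref$f_measure[by_ref$reference == "u"],
               mean(c(score_counts(5, 5, 5)$f_measure,
                      score_counts(3, 4, 4)$f_measure)))
  # mean of F1 scores as printed
  expect_equal(round_half_up(mean(c(0.53, 0.43, 0.60)), 2), 0.52)
  # mean alignment sizes from the packaged study table
  sizes <- study_table("alignment_sizes")
  expect_equal(round_half_up(mean(
    sizes$n_whole[sizes$pair == "ORDO-SNOMEDCT"])), 5726)

  # undefined scores are dropped with a message, not averaged as zero
  with_na <- rbind(df, as.data.frame(score_counts(0, 0, 4, "u")))
  expect_message(m <- aggregate_means(with_na, group_by = "reference"),
                 "undefined")
  expect_equal(m$precision[m$reference == "u"],
               mean(c(0.5, 3 / 7)))
  expect_error(aggregate_means(list()), "non-empty|aggregate")
})
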