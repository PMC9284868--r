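#' Configuration for synthetic matching scenarios
#'
#' Describes a pair of synthetic ontologies and a simulated matcher, shaped
#' after the statistical structure of real biomedical terminology matching:
#' each ontology is a rooted DAG whose direct root children act as a small
#' set of top-level categories (19 by default, the number of top-level
#' classes in SNOMED CT and NCIt); some category pairs are "manually
#' matched" across the two ontologies; shared concepts appear once per
#' ontology under matched categories and form the ground-truth equivalence
#' alignment; CUI annotations cover a fraction of the shared concepts; and a
#' simulated matcher recovers ground-truth mappings at a configured recall
#' while planting a configured number of false mappings, a fraction of
#' which join unmatched category pairs (and are therefore detectable by the
#' top-level hierarchy filter).
#'
#' @param seed integer seed; the scenario is a pure function of the
#'   configuration including the seed.
#' @param n_categories_a,n_categories_b number of top-level categories.
#' @param category_map_fraction fraction of the smaller category set that is
#'   manually matched across the pair (pairing is index-wise).
#' @param classes_per_category classes generated under each category.
#' @param max_depth maximum depth of a class below its category.
#' @param n_extra_parent_edges multi-parent (diamond) edges added within
#'   categories to exercise multiple inheritance.
#' @param shared_concept_fraction fraction of each matched category's
#'   classes that have a counterpart in the other ontology (applied as an
#'   exact per-category count).
#' @param cui_coverage probability that a shared concept pair carries a
#'   common CUI in both ontologies.
#' @param matcher_recall probability the simulated matcher recovers a
#'   ground-truth mapping.
#' @param n_false_mappings number of planted false mappings.
#' @param cross_category_fraction fraction (gamma) of planted false
#'   mappings joining classes under category pairs that are not manually
#'   matched; applied as an exact count (round half up), not by sampling,
#'   so filter behaviour is deterministic given the counts.
#' @param ontology_id_a,ontology_id_b short ontology names.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_categories_a = 19L,
                             n_categories_b = 19L,
                             category_map_fraction = 13 / 19,
                             classes_per_category = 40L,
                             max_depth = 4L,
                             n_extra_parent_edges = 10L,
                             shared_concept_fraction = 0.5,
                             cui_coverage = 0.85,
                             matcher_recall = 0.66,
                             n_false_mappings = 200L,
                             cross_category_fraction = 0.2,
                             ontology_id_a = "ONTA",
                             ontology_id_b = "ONTB") {
  cfg <- list(seed = as.integer(seed),
              n_categories_a = as.integer(n_categories_a),
              n_categories_b = as.integer(n_categories_b),
              category_map_fraction = as.numeric(category_map_fraction),
              classes_per_category = as.integer(classes_per_category),
              max_depth = as.integer(max_depth),
              n_extra_parent_edges = as.integer(n_extra_parent_edges),
              shared_concept_fraction = as.numeric(shared_concept_fraction),
              cui_coverage = as.numeric(cui_coverage),
              matcher_recall = as.numeric(matcher_recall),
              n_false_mappings = as.integer(n_false_mappings),
              cross_category_fraction = as.numeric(cross_category_fraction),
              ontology_id_a = as.character(ontology_id_a),
              ontology_id_b = as.character(ontology_id_b))
  fracs <- c("category_map_fraction", "shared_concept_fraction",
             "cui_coverage", "matcher_recall", "cross_category_fraction")
  for (f in fracs) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(f, " must lie in [0, 1]")
    }
  }
  counts <- c("n_categories_a", "n_categories_b", "classes_per_category",
              "max_depth")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1) stop(f, " must be a positive count")
  }
  if (cfg$n_false_mappings < 0 || cfg$n_extra_parent_edges < 0) {
    stop("n_false_mappings and n_extra_parent_edges must be non-negative")
  }
  if (identical(cfg$ontology_id_a, cfg$ontology_id_b)) {
    stop("ontology ids must differ")
  }
  structure(cfg, class = "synthetic_config")
}

# Internal: random tree under one category node, generated depth by depth.
# Returns a named list of parent vectors for the class iris.
build_category_tree <- function(cat_iri, class_iris, max_depth) {
  n <- length(class_iris)
  parents <- stats::setNames(vector("list", n), class_iris)
  if (n == 0) return(parents)
  depth <- sort(sample.int(max_depth, n, replace = TRUE))
  depth[[1]] <- 1L
  if (n > 1) {
    for (i in 2:n) depth[[i]] <- min(depth[[i]], depth[[i - 1]] + 1L)
  }
  for (d in sort(unique(depth))) {
    at_d <- class_iris[depth == d]
    pool <- if (d == 1L) cat_iri else class_iris[depth == d - 1L]
    picks <- pool[sample.int(length(pool), length(at_d), replace = TRUE)]
    for (j in seq_along(at_d)) parents[[at_d[[j]]]] <- picks[[j]]
  }
  attr(parents, "depth") <- stats::setNames(depth, class_iris)
  parents
}

build_synthetic_ontology <- function(id, n_categories, classes_per_category,
                                     max_depth, n_extra_parent_edges) {
  root <- paste0(id, ":root")
  cats <- sprintf("%s:T%02d", id, seq_len(n_categories))
  iris <- c(root, cats)
  parents <- c(stats::setNames(list(character(0)), root),
               stats::setNames(rep(list(root), n_categories), cats))
  category_of <- character(0)
  depth_of <- integer(0)
  class_lists <- vector("list", n_categories)
  for (i in seq_len(n_categories)) {
    cls <- sprintf("%s:C%02d_%03d", id, i, seq_len(classes_per_category))
    tree <- build_category_tree(cats[[i]], cls, max_depth)
    depth_of <- c(depth_of, attr(tree, "depth"))
    attr(tree, "depth") <- NULL
    parents <- c(parents, tree)
    iris <- c(iris, cls)
    category_of <- c(category_of, stats::setNames(rep(i, length(cls)), cls))
    class_lists[[i]] <- cls
  }
  # diamond edges: an extra parent from a strictly shallower class of the
  # same category keeps the graph acyclic and the category unique
  if (n_extra_parent_edges > 0) {
    deep <- names(depth_of)[depth_of >= 2L]
    if (length(deep)) {
      picks <- deep[sample.int(length(deep),
                               min(n_extra_parent_edges, length(deep)))]
      for (cls in picks) {
        cat_i <- category_of[[cls]]
        pool <- class_lists[[cat_i]]
        shallower <- pool[depth_of[pool] < depth_of[[cls]]]
        shallower <- setdiff(shallower, parents[[cls]])
        if (length(shallower)) {
          extra <- shallower[[sample.int(length(shallower), 1)]]
          parents[[cls]] <- c(parents[[cls]], extra)
        }
      }
    }
  }
  list(root = root, categories = cats, iris = iris, parents = parents,
       category_of = category_of, class_lists = class_lists)
}

#' Generate a synthetic matching scenario
#'
#' Builds two rooted ontologies, the ground-truth equivalence alignment
#' between their shared concepts, CUI annotation tables for both, and the
#' set of matched top-level category pairs. Shared concepts exist only
#' under matched category pairs; with `cui_coverage = 1` the CUI-based
#' reference alignment equals the ground truth exactly. Deterministic given
#' the configuration (including its seed).
#'
#' @param config a [synthetic_config()].
#' @return an object of class `matching_scenario` with elements
#'   `ontology_a`, `ontology_b`, `ground_truth` ([alignment()]), `cui_a`,
#'   `cui_b` ([cui_table()]s), `top_level_mappings`
#'   ([top_level_mapping_set()]), `category_of_a`, `category_of_b` (named
#'   category indices), and `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  k <- as.integer(round_half_up(
    config$category_map_fraction *
      min(config$n_categories_a, config$n_categories_b)))
  if (k == 0 && config$shared_concept_fraction > 0) {
    stop("infeasible configuration: shared concepts requested but no ",
         "category pair is matched (category_map_fraction too small)")
  }
  with_seed(config$seed, {
    onta <- build_synthetic_ontology(config$ontology_id_a,
                                     config$n_categories_a,
                                     config$classes_per_category,
                                     config$max_depth,
                                     config$n_extra_parent_edges)
    ontb <- build_synthetic_ontology(config$ontology_id_b,
                                     config$n_categories_b,
                                     config$classes_per_category,
                                     config$max_depth,
                                     config$n_extra_parent_edges)

    n_shared <- as.integer(round_half_up(
      config$shared_concept_fraction * config$classes_per_category))
    gt_src <- gt_tgt <- character(0)
    shared_stem <- character(0)
    for (i in seq_len(k)) {
      if (n_shared == 0) break
      a_cls <- sort(sample(onta$class_lists[[i]], n_shared))
      b_cls <- sort(sample(ontb$class_lists[[i]], n_shared))
      gt_src <- c(gt_src, a_cls)
      gt_tgt <- c(gt_tgt, b_cls)
      shared_stem <- c(shared_stem, sprintf("concept %02d-%03d", i,
                                            seq_len(n_shared)))
    }

    # labels: shared pairs get case variants of a common stem (the lexical
    # near-duplicate failure mode of real matchers); other classes get
    # ontology-specific labels
    label_a <- stats::setNames(
      paste(config$ontology_id_a, "class",
            seq_along(c(onta$iris))), onta$iris)
    label_b <- stats::setNames(
      paste(config$ontology_id_b, "class",
            seq_along(c(ontb$iris))), ontb$iris)
    totitle <- function(x) gsub("\\b(\\w)", "\\U\\1", x, perl = TRUE)
    label_a[gt_src] <- totitle(shared_stem)
    label_b[gt_tgt] <- shared_stem
    label_a[onta$root] <- "Thing"; label_b[ontb$root] <- "Thing"
    label_a[onta$categories] <- sprintf("Category %02d (%s)",
                                        seq_along(onta$categories),
                                        config$ontology_id_a)
    label_b[ontb$categories] <- sprintf("Category %02d (%s)",
                                        seq_along(ontb$categories),
                                        config$ontology_id_b)
    # a few cross-category lexical near-duplicates (labels play no
    # computational role downstream)
    if (length(shared_stem) >= 2) {
      n_dup <- min(5L, length(shared_stem))
      dup_pool <- setdiff(onta$iris[-1], c(gt_src, onta$categories))
      if (length(dup_pool) >= n_dup) {
        dup_cls <- sample(dup_pool, n_dup)
        label_a[dup_cls] <- totitle(sample(shared_stem, n_dup))
      }
    }

    # CUI annotations: covered shared pairs get one common CUI; uncovered
    # shared pairs and a fraction of unshared classes get private CUIs
    cui_counter <- 0L
    next_cui <- function(n = 1L) {
      out <- sprintf("C%07d", cui_counter + seq_len(n))
      cui_counter <<- cui_counter + n
      out
    }
    cui_a <- list(); cui_b <- list()
    if (length(gt_src)) {
      covered <- stats::runif(length(gt_src)) < config$cui_coverage
      common <- next_cui(sum(covered))
      j <- 0L
      for (idx in seq_along(gt_src)) {
        if (covered[[idx]]) {
          j <- j + 1L
          cui_a[[gt_src[[idx]]]] <- common[[j]]
          cui_b[[gt_tgt[[idx]]]] <- common[[j]]
        } else {
          cui_a[[gt_src[[idx]]]] <- next_cui()
          cui_b[[gt_tgt[[idx]]]] <- next_cui()
        }
      }
    }
    for (cls in setdiff(onta$iris, c(onta$root, onta$categories, gt_src))) {
      if (stats::runif(1) < 0.2) cui_a[[cls]] <- next_cui()
    }
    for (cls in setdiff(ontb$iris, c(ontb$root, ontb$categories, gt_tgt))) {
      if (stats::runif(1) < 0.2) cui_b[[cls]] <- next_cui()
    }

    ontology_a <- ontology(config$ontology_id_a, onta$iris, onta$parents,
                           labels = label_a, cuis = cui_a)
    ontology_b <- ontology(config$ontology_id_b, ontb$iris, ontb$parents,
                           labels = label_b, cuis = cui_b)
    gt <- alignment(config$ontology_id_a, config$ontology_id_b,
                    sort_mappings(mappings(gt_src, gt_tgt)),
                    provenance = "ground-truth")
    tlms <- top_level_mapping_set(
      c(config$ontology_id_a, config$ontology_id_b),
      data.frame(iri_a = onta$categories[seq_len(k)],
                 iri_b = ontb$categories[seq_len(k)],
                 stringsAsFactors = FALSE),
      onto_a = ontology_a, onto_b = ontology_b)

    structure(list(ontology_a = ontology_a, ontology_b = ontology_b,
                   ground_truth = gt,
                   cui_a = cui_table(config$ontology_id_a, cui_a),
                   cui_b = cui_table(config$ontology_id_b, cui_b),
                   top_level_mappings = tlms,
                   category_of_a = onta$category_of,
                   category_of_b = ontb$category_of,
                   n_matched_categories = k,
                   config = config),
              class = "matching_scenario")
  })
}

#' @export
print.matching_scenario <- function(x, ...) {
  cat(sprintf(paste0("matching scenario %s - %s: %d + %d classes, ",
                     "%d ground-truth mapping(s), %d matched categories\n"),
              x$config$ontology_id_a, x$config$ontology_id_b,
              length(x$ontology_a$iris), length(x$ontology_b$iris),
              nrow(x$ground_truth$mappings), x$n_matched_categories))
  invisible(x)
}

#' Degrade a reference alignment to emulate incompleteness
#'
#' Real reference alignments (a BioPortal-style lexical baseline, a
#' UMLS-style silver standard) are incomplete. This retains each mapping
#' independently with probability `completeness`, deterministically under
#' the seed.
#'
#' @param ground_truth an [alignment()].
#' @param completeness retention probability in `[0, 1]`.
#' @param seed integer seed.
#' @return the degraded [alignment()].
#' @export
degrade_reference <- function(ground_truth, completeness, seed) {
  stopifnot(inherits(ground_truth, "alignment"))
  completeness <- as.numeric(completeness)
  if (is.na(completeness) || completeness < 0 || completeness > 1) {
    stop("completeness must lie in [0, 1]")
  }
  df <- ground_truth$mappings
  keep <- with_seed(seed, stats::runif(nrow(df)) < completeness)
  alignment(ground_truth$source_ontology_id,
            ground_truth$target_ontology_id,
            df[keep, , drop = FALSE],
            provenance = sprintf("%s@completeness=%g",
                                 ground_truth$provenance, completeness))
}

# Internal: sample n distinct class pairs from the given candidate
# categories, avoiding forbidden keys. Errors when candidates run out.
sample_false_pairs <- function(scenario, n, category_pairs, forbidden_keys,
                               what) {
  if (n == 0) {
    return(data.frame(source_iri = character(), target_iri = character(),
                      stringsAsFactors = FALSE))
  }
  if (!nrow(category_pairs)) {
    stop("not enough candidate class pairs for ", n, " ", what, " mapping(s)")
  }
  a_lists <- split(names(scenario$category_of_a), scenario$category_of_a)
  b_lists <- split(names(scenario$category_of_b), scenario$category_of_b)
  src <- tgt <- character(n)
  got <- 0L
  seen <- forbidden_keys
  attempts <- 0L
  max_attempts <- 200L * n + 1000L
  while (got < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("not enough candidate class pairs for ", n, " ", what,
           " mapping(s)")
    }
    row <- category_pairs[sample.int(nrow(category_pairs), 1L), ]
    a_pool <- a_lists[[as.character(row$i)]]
    b_pool <- b_lists[[as.character(row$j)]]
    if (!length(a_pool) || !length(b_pool)) next
    a <- a_pool[[sample.int(length(a_pool), 1L)]]
    b <- b_pool[[sample.int(length(b_pool), 1L)]]
    key <- pair_key(a, b)
    if (key %in% seen) next
    got <- got + 1L
    src[[got]] <- a; tgt[[got]] <- b
    seen <- c(seen, key)
  }
  data.frame(source_iri = src, target_iri = tgt, stringsAsFactors = FALSE)
}

#' Simulate a matching system's output
#'
#' Emulates a matcher at the error-rate level (no lexical matching is
#' simulated): each ground-truth mapping is recovered with probability
#' `matcher_recall`, and `n_false_mappings` false mappings are planted. Of
#' these, an exact count `round_half_up(cross_category_fraction *
#' n_false_mappings)` join classes under category pairs that are NOT in the
#' top-level mapping set (detectable by the hierarchy filter); the rest
#' join distinct, non-equivalent classes under matched category pairs
#' (invisible to the filter). Every output mapping carries a `planted`
#' column (`"true"`, `"false_same_category"`, `"false_cross_category"`) for
#' test assertions; the column plays no role in mapping identity.
#'
#' @param scenario a [generate_scenario()] result.
#' @param config a [synthetic_config()]; defaults to the scenario's own.
#' @param seed integer seed for the matcher's randomness.
#' @return an [alignment()] normalized to the scenario's pair order.
#' @export
simulate_matcher <- function(scenario, config = scenario$config,
                             seed = config$seed) {
  stopifnot(inherits(scenario, "matching_scenario"),
            inherits(config, "synthetic_config"))
  gt <- scenario$ground_truth$mappings
  gt_keys <- pair_key(gt$source_iri, gt$target_iri)
  k <- scenario$n_matched_categories
  n_cross <- as.integer(round_half_up(
    config$cross_category_fraction * config$n_false_mappings))
  n_same <- config$n_false_mappings - n_cross

  with_seed(seed, {
    recalled <- gt[stats::runif(nrow(gt)) < config$matcher_recall, ,
                   drop = FALSE]

    matched_pairs <- if (k > 0) {
      data.frame(i = seq_len(k), j = seq_len(k))
    } else data.frame(i = integer(), j = integer())
    all_pairs <- expand.grid(i = seq_len(config$n_categories_a),
                             j = seq_len(config$n_categories_b))
    matched_key <- paste(matched_pairs$i, matched_pairs$j)
    cross_pairs <- all_pairs[!paste(all_pairs$i, all_pairs$j) %in%
                               matched_key, , drop = FALSE]

    same <- sample_false_pairs(scenario, n_same, matched_pairs,
                               gt_keys, "same-category false")
    cross <- sample_false_pairs(
      scenario, n_cross, cross_pairs,
      c(gt_keys, pair_key(same$source_iri, same$target_iri)),
      "cross-category false")

    out <- rbind(
      if (nrow(recalled))
        cbind(recalled[, c("source_iri", "target_iri")],
              planted = "true") else NULL,
      if (nrow(same)) cbind(same, planted = "false_same_category") else NULL,
      if (nrow(cross)) cbind(cross, planted = "false_cross_category")
      else NULL)
    if (is.null(out)) {
      out <- data.frame(source_iri = character(), target_iri = character(),
                        planted = character(), stringsAsFactors = FALSE)
    }
    df <- mappings(out$source_iri, out$target_iri,
                   confidence = round(stats::runif(nrow(out), 0.5, 1), 4))
    df$planted <- out$planted
    alignment(config$ontology_id_a, config$ontology_id_b,
              sort_mappings(df),
              provenance = sprintf("simulated-matcher(seed=%d)", seed))
  })
}

#' Write a scenario's files to a directory
#'
#' Emits the full scenario in the package's exchange dialects: both
#' ontologies as TSV and OWL, the ground truth as Alignment API RDF and
#' TSV, both CUI tables, and the top-level mapping table.
#'
#' @param scenario a [generate_scenario()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "matching_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ida <- scenario$config$ontology_id_a
  idb <- scenario$config$ontology_id_b
  paths <- c(
    ontology_a_tsv = file.path(dir, paste0(ida, ".tsv")),
    ontology_b_tsv = file.path(dir, paste0(idb, ".tsv")),
    ontology_a_owl = file.path(dir, paste0(ida, ".owl")),
    ontology_b_owl = file.path(dir, paste0(idb, ".owl")),
    ground_truth_rdf = file.path(dir, "ground_truth.rdf"),
    ground_truth_tsv = file.path(dir, "ground_truth.tsv"),
    cui_a = file.path(dir, paste0(ida, "_cuis.tsv")),
    cui_b = file.path(dir, paste0(idb, "_cuis.tsv")),
    top_level = file.path(dir, "top_level_mappings.tsv"))
  write_ontology_tsv(scenario$ontology_a, paths[["ontology_a_tsv"]])
  write_ontology_tsv(scenario$ontology_b, paths[["ontology_b_tsv"]])
  write_ontology_owl(scenario$ontology_a, paths[["ontology_a_owl"]])
  write_ontology_owl(scenario$ontology_b, paths[["ontology_b_owl"]])
  write_alignment_rdf(scenario$ground_truth, paths[["ground_truth_rdf"]])
  write_alignment_tsv(scenario$ground_truth, paths[["ground_truth_tsv"]])
  write_cui_table(scenario$cui_a, paths[["cui_a"]])
  write_cui_table(scenario$cui_b, paths[["cui_b"]])
  utils::write.table(scenario$top_level_mappings$pairs,
                     paths[["top_level"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}
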