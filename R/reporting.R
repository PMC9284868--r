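read_alignment_any <- function(x, ...) {
  if (inherits(x, "alignment")) return(x)
  if (!is.character(x) || length(x) != 1) {
    stop("expected an alignment object or a file path")
  }
  if (!file.exists(x)) stop("alignment file not found: ", x)
  if (grepl("\\.(rdf|xml|owl)$", x, ignore.case = TRUE)) {
    read_alignment_rdf(x, ...)
  } else {
    read_alignment_tsv(x, ...)
  }
}

write_report_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  # scores to 2 decimals in reports; raw values stay on the R objects
  for (col in names(df)[num]) {
    if (!all(df[[col]] == as.integer(df[[col]]), na.rm = TRUE)) {
      df[[col]] <- round_half_up(df[[col]], 2)
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Evaluate alignments against references and write CSV reports
#'
#' Scores every alignment against every reference and writes two CSV files
#' to `out_dir`: `evaluation.csv` (one row per alignment-reference
#' combination, with TP/FP/FN counts and precision/recall/F-measure to two
#' decimals) and `evaluation_means.csv` (mean scores per reference across
#' alignments, the mean-of-scores aggregation).
#'
#' @param alignments named list of [alignment()] objects or file paths
#'   (Alignment API RDF or TSV).
#' @param references named list of reference alignments or file paths.
#' @param pair length-2 character vector: the pair order everything is
#'   normalized to.
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the two data frames (`per_alignment`,
#'   `means`) carrying unrounded scores.
#' @export
run_evaluate <- function(alignments, references, pair, out_dir) {
  if (!length(alignments)) stop("at least one alignment is required")
  if (!length(references)) stop("at least one reference is required")
  alignments <- lapply(alignments, read_alignment_any)
  references <- lapply(references, read_alignment_any)
  aln_names <- names(alignments) %||%
    vapply(alignments, `[[`, character(1), "provenance")
  ref_names <- names(references) %||%
    vapply(references, `[[`, character(1), "provenance")
  alignments <- lapply(alignments, normalize_alignment, pair_order = pair)
  references <- lapply(references, normalize_alignment, pair_order = pair)

  rows <- list()
  for (i in seq_along(alignments)) {
    for (j in seq_along(references)) {
      res <- evaluate_alignment(alignments[[i]], references[[j]],
                                reference_label = ref_names[[j]])
      row <- as.data.frame(res)
      row <- cbind(data.frame(alignment = aln_names[[i]],
                              stringsAsFactors = FALSE), row)
      rows[[length(rows) + 1]] <- row
    }
  }
  per <- do.call(rbind, rows)
  means <- aggregate_means(per, group_by = "reference")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_report_csv(per, file.path(out_dir, "evaluation.csv"))
  write_report_csv(means, file.path(out_dir, "evaluation_means.csv"))
  invisible(list(per_alignment = per, means = means))
}

#' Run the top-level hierarchy analysis and write CSV reports
#'
#' Analyzes each alignment's top-level hierarchy consistency against the
#' manual top-level mapping set, discards inconsistent false positives
#' (mappings that are a true positive of no reference), and re-scores.
#' Writes `hierarchy_counts.csv` (inconsistent and candidate-FP counts with
#' percentage labels, plus an unresolvable-mapping count) and
#' `hierarchy_scores.csv` (before/after precision and F-measure per
#' reference, with "+0.0x"-style deltas; recall is unchanged by
#' construction).
#'
#' @param alignments named list of alignments or paths.
#' @param onto_a,onto_b [ontology()] objects or paths (TSV or OWL).
#' @param tlms a [top_level_mapping_set()] or path to its TSV.
#' @param references named list of reference alignments or paths.
#' @param pair length-2 pair order.
#' @param out_dir output directory.
#' @return invisibly, a list with data frames `counts` and `scores`.
#' @export
run_hierarchy <- function(alignments, onto_a, onto_b, tlms, references,
                          pair, out_dir) {
  read_ont <- function(x) {
    if (inherits(x, "ontology")) return(x)
    if (grepl("\\.(owl|rdf|xml)$", x, ignore.case = TRUE)) {
      load_ontology_owl(x)
    } else load_ontology_tsv(x)
  }
  onto_a <- read_ont(onto_a)
  onto_b <- read_ont(onto_b)
  if (!inherits(tlms, "top_level_mapping_set")) {
    tlms <- load_top_level_mappings(tlms, onto_a = onto_a, onto_b = onto_b)
  }
  alignments <- lapply(alignments, read_alignment_any)
  references <- lapply(references, read_alignment_any)
  aln_names <- names(alignments) %||%
    vapply(alignments, `[[`, character(1), "provenance")
  alignments <- lapply(alignments, normalize_alignment, pair_order = pair)
  references <- lapply(references, normalize_alignment, pair_order = pair)
  if (is.null(names(references))) {
    names(references) <- vapply(references, `[[`, character(1), "provenance")
  }

  count_rows <- list(); score_rows <- list()
  for (i in seq_along(alignments)) {
    al <- alignments[[i]]
    keys <- alignment_keys(al)
    tp_keys <- character(0)
    for (ref in references) {
      tp_keys <- c(tp_keys, intersect(keys, alignment_keys(ref)))
    }
    tp_union <- al$mappings[keys %in% unique(tp_keys),
                            c("source_iri", "target_iri"), drop = FALSE]
    analysis <- analyze_alignment(al, onto_a, onto_b, tlms,
                                  tp_union = tp_union)
    count_rows[[i]] <- data.frame(
      alignment = aln_names[[i]],
      n_mappings = nrow(al$mappings),
      inconsistent = analysis$inconsistent_count,
      inconsistent_fp = analysis$inconsistent_fp_count,
      unresolvable = analysis$unresolvable_count,
      pct_inconsistent =
        format_percent(100 * analysis$proportion_inconsistent),
      pct_inconsistent_fp =
        format_percent(100 * analysis$proportion_inconsistent_fp),
      stringsAsFactors = FALSE)
    rr <- filter_and_reevaluate(al, analysis, references)
    sr <- rr$summary
    sr <- cbind(data.frame(alignment = aln_names[[i]],
                           stringsAsFactors = FALSE), sr)
    score_rows[[i]] <- sr
  }
  counts <- do.call(rbind, count_rows)
  scores <- do.call(rbind, score_rows)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_report_csv(counts, file.path(out_dir, "hierarchy_counts.csv"))
  write_report_csv(scores, file.path(out_dir, "hierarchy_scores.csv"))
  invisible(list(counts = counts, scores = scores))
}

#' Run the full assessment pipeline on a synthetic scenario
#'
#' End-to-end orchestration: generate a synthetic scenario, simulate
#' several matchers, build the CUI-based reference plus a degraded
#' baseline reference, evaluate whole-ontology and module-restricted
#' alignments, run the top-level hierarchy analysis with before/after
#' re-scoring, evaluate vote-based consensus alignments, and write all
#' reports plus a manifest (package version, seed, input file digests)
#' under `out_dir`. Reruns with the same configuration produce
#' byte-identical CSVs.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory.
#' @param n_matchers number of simulated matching systems.
#' @param votes vote thresholds for consensus alignments.
#' @param baseline_completeness completeness of the degraded lexical
#'   baseline reference (the CUI reference plays the silver-standard role).
#' @param module_seed_fraction fraction of ground-truth source classes used
#'   as the module seed signature (extended with ancestors before star
#'   extraction).
#' @return invisibly, a list of the report data frames and the file
#'   manifest.
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir,
                         n_matchers = 3L, votes = c(2L, 3L),
                         baseline_completeness = 0.5,
                         module_seed_fraction = 0.25) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pair <- c(config$ontology_id_a, config$ontology_id_b)

  scenario <- generate_scenario(config)
  scenario_dir <- file.path(out_dir, "scenario")
  scenario_files <- write_scenario(scenario, scenario_dir)

  matcher_names <- sprintf("matcher%d", seq_len(n_matchers))
  alignments <- stats::setNames(lapply(seq_len(n_matchers), function(i) {
    simulate_matcher(scenario, config, seed = config$seed + i)
  }), matcher_names)
  aln_dir <- file.path(out_dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  aln_files <- character(0)
  for (nm in matcher_names) {
    f <- file.path(aln_dir, paste0(nm, ".rdf"))
    write_alignment_rdf(alignments[[nm]], f)
    aln_files[[nm]] <- f
  }

  silver <- build_cui_reference(scenario$cui_a, scenario$cui_b)
  silver$provenance <- "cui-silver"
  baseline <- degrade_reference(scenario$ground_truth,
                                baseline_completeness,
                                seed = config$seed + 101L)
  baseline$provenance <- "lexical-baseline"
  references <- list(cui_silver = silver, baseline = baseline)

  report_dir <- file.path(out_dir, "reports")
  dir.create(report_dir, showWarnings = FALSE)

  whole <- run_evaluate(alignments, references, pair,
                        file.path(report_dir, "whole"))

  # module scope: seed = a sample of ground-truth source classes, extended
  # with ancestors, star modules on both sides
  gt_src <- scenario$ground_truth$mappings$source_iri
  gt_tgt <- scenario$ground_truth$mappings$target_iri
  n_seed <- max(1L, as.integer(round_half_up(
    module_seed_fraction * length(gt_src))))
  sel <- with_seed(config$seed + 202L,
                   sample.int(length(gt_src), n_seed))
  seed_a <- extend_seed_with_ancestors(scenario$ontology_a, gt_src[sel])
  seed_b <- extend_seed_with_ancestors(scenario$ontology_b, gt_tgt[sel])
  module_a <- extract_module(scenario$ontology_a, seed_a, "star")
  module_b <- extract_module(scenario$ontology_b, seed_b, "star")
  restrict_alignment <- function(al) {
    restrict_reference_to_module(al, module_a, module_b)
  }
  module_refs <- lapply(references, restrict_alignment)
  module_alns <- lapply(lapply(alignments, normalize_alignment,
                               pair_order = pair), restrict_alignment)
  module <- run_evaluate(module_alns, module_refs, pair,
                         file.path(report_dir, "module"))
  module_sizes <- data.frame(
    ontology = pair,
    n_module = c(length(module_a$iris), length(module_b$iris)),
    n_total = c(length(scenario$ontology_a$iris),
                length(scenario$ontology_b$iris)),
    pct = c(module_stats(scenario$ontology_a, module_a)$pct_label,
            module_stats(scenario$ontology_b, module_b)$pct_label),
    stringsAsFactors = FALSE)
  write_report_csv(module_sizes, file.path(report_dir, "module_sizes.csv"))

  hier <- run_hierarchy(alignments, scenario$ontology_a,
                        scenario$ontology_b,
                        scenario$top_level_mappings, references, pair,
                        file.path(report_dir, "hierarchy"))

  cons_rows <- list()
  normalized <- lapply(alignments, normalize_alignment, pair_order = pair)
  for (v in votes) {
    cons <- consensus_alignment(normalized, v)
    for (rn in names(references)) {
      ref <- normalize_alignment(references[[rn]], pair)
      res <- evaluate_alignment(cons, ref, reference_label = rn)
      row <- as.data.frame(res)
      row <- cbind(data.frame(votes = v, n_mappings = nrow(cons$mappings),
                              stringsAsFactors = FALSE), row)
      cons_rows[[length(cons_rows) + 1]] <- row
    }
  }
  consensus_df <- do.call(rbind, cons_rows)
  write_report_csv(consensus_df, file.path(report_dir, "consensus.csv"))

  inputs <- c(scenario_files, aln_files)
  manifest <- list(
    package = "ontalign",
    version = as.character(utils::packageVersion("ontalign")),
    seed = config$seed,
    config = unclass(config),
    inputs = as.list(stats::setNames(unname(tools::md5sum(inputs)),
                                     basename(unname(inputs)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(scenario = scenario, evaluation_whole = whole,
                 evaluation_module = module, hierarchy = hier,
                 consensus = consensus_df,
                 manifest = manifest))
}
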