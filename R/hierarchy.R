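#' Construct a top-level mapping set
#'
#' A manually curated set of pairs of top-level classes (direct children of
#' the root) considered semantically equivalent across an ontology pair,
#' e.g. NCIt "Anatomic Structure, System, or Substance" with SNOMED CT
#' "Body structure". Many-to-many pairs are allowed: one top-level class may
#' participate in several pairs.
#'
#' @param pair length-2 character vector of ontology ids (A, B).
#' @param pairs data frame with character columns `iri_a`, `iri_b`.
#' @param onto_a,onto_b optional [ontology()] objects; when supplied, every
#'   iri is validated to be a top-level class of its ontology and a
#'   violating row is reported by number.
#' @return an object of class `top_level_mapping_set`.
#' @export
top_level_mapping_set <- function(pair, pairs, onto_a = NULL, onto_b = NULL) {
  pair <- as.character(pair)
  if (length(pair) != 2) stop("`pair` must name two ontologies")
  missing <- setdiff(c("iri_a", "iri_b"), names(pairs))
  if (length(missing)) {
    stop("top-level mapping table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  pairs <- data.frame(iri_a = as.character(pairs$iri_a),
                      iri_b = as.character(pairs$iri_b),
                      stringsAsFactors = FALSE)
  pairs <- pairs[!duplicated(pair_key(pairs$iri_a, pairs$iri_b)), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  check_side <- function(iris, ont, side) {
    if (is.null(ont)) return(invisible())
    tls <- top_level_classes(ont)
    bad <- which(!iris %in% tls)
    if (length(bad)) {
      stop("row ", bad[[1]], ": <", iris[[bad[[1]]]],
           "> is not a top-level class of ontology '",
           ont$ontology_id, "' (column ", side, ")")
    }
  }
  check_side(pairs$iri_a, onto_a, "iri_a")
  check_side(pairs$iri_b, onto_b, "iri_b")
  structure(list(pair = pair, pairs = pairs),
            class = "top_level_mapping_set")
}

#' Load a top-level mapping set from TSV
#'
#' Reads a TSV with columns `iri_a`, `iri_b` (additional columns such as
#' labels or an ontology-pair tag are allowed and ignored, except `pair`
#' which can be used for filtering).
#'
#' @param path path to a TSV file.
#' @param onto_a,onto_b optional [ontology()] objects used for validation,
#'   and for the ontology-id pair when given.
#' @param pair optional: either the value to filter the file's `pair` column
#'   on, or (when the file has no `pair` column) the length-2 id pair.
#' @return a [top_level_mapping_set()].
#' @export
load_top_level_mappings <- function(path, onto_a = NULL, onto_b = NULL,
                                    pair = NULL) {
  if (!file.exists(path)) stop("top-level mapping file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          colClasses = "character",
                          na.strings = character(), check.names = FALSE)
  if (!is.null(pair) && length(pair) == 1 && "pair" %in% names(df)) {
    df <- df[df$pair == pair, , drop = FALSE]
  }
  ids <- c(
    if (!is.null(onto_a)) onto_a$ontology_id else
      if (length(pair) == 2) pair[[1]] else "A",
    if (!is.null(onto_b)) onto_b$ontology_id else
      if (length(pair) == 2) pair[[2]] else "B")
  top_level_mapping_set(ids, df, onto_a = onto_a, onto_b = onto_b)
}

#' @export
print.top_level_mapping_set <- function(x, ...) {
  cat(sprintf("top-level mapping set %s - %s: %d pair(s)\n",
              x$pair[[1]], x$pair[[2]], nrow(x$pairs)))
  invisible(x)
}

#' Is a mapping consistent with the top-level hierarchy mappings?
#'
#' A mapping is hierarchy-consistent when at least one pair formed by a
#' top-level ancestor of its source class and a top-level ancestor of its
#' target class is present in the manually curated top-level mapping set.
#' With multiple inheritance the rule is existential: any matching ancestor
#' pair suffices, so a mapping with one plausible category match is never
#' flagged.
#'
#' @param source_iri,target_iri class identifiers (neither may be a root).
#' @param onto_a,onto_b [ontology()] objects containing the classes.
#' @param tlms a [top_level_mapping_set()].
#' @return `TRUE` or `FALSE`.
#' @export
mapping_hierarchy_consistent <- function(source_iri, target_iri,
                                         onto_a, onto_b, tlms) {
  tla <- top_level_ancestors(onto_a, source_iri)
  tlb <- top_level_ancestors(onto_b, target_iri)
  any(tlms$pairs$iri_a %in% tla & tlms$pairs$iri_b %in% tlb)
}

#' Analyze the top-level hierarchy consistency of an alignment
#'
#' Partitions an alignment into hierarchy-consistent and inconsistent
#' mappings (see [mapping_hierarchy_consistent()]). Mappings whose classes
#' are missing from the supplied ontologies cannot be analyzed; they are
#' reported in a separate `unresolvable` bucket rather than silently
#' counted either way. Among the inconsistent mappings, those that are not
#' a true positive of any reference (`tp_union`) are counted separately:
#' these are the candidates the filter may discard.
#'
#' @param al a normalized [alignment()].
#' @param onto_a,onto_b [ontology()] objects for the pair.
#' @param tlms a [top_level_mapping_set()].
#' @param tp_union data frame with columns `source_iri`, `target_iri`: the
#'   union of true-positive mappings across all available references (may be
#'   `NULL` or empty when no reference exists).
#' @return an object of class `hierarchy_analysis` with elements
#'   `consistent`, `inconsistent`, `unresolvable` (data frames of mappings),
#'   `discardable` (inconsistent and not in `tp_union`), counts
#'   `inconsistent_count` and `inconsistent_fp_count`, and proportions
#'   `proportion_inconsistent`, `proportion_inconsistent_fp` over the whole
#'   alignment (`NA` for an empty alignment).
#' @export
analyze_alignment <- function(al, onto_a, onto_b, tlms, tp_union = NULL) {
  stopifnot(inherits(al, "alignment"),
            inherits(tlms, "top_level_mapping_set"))
  df <- al$mappings
  n <- nrow(df)
  tp_keys <- if (is.null(tp_union) || !nrow(tp_union)) character(0) else
    unique(pair_key(tp_union$source_iri, tp_union$target_iri))

  resolvable <- df$source_iri %in% onto_a$iris &
    df$target_iri %in% onto_b$iris &
    df$source_iri != onto_a$root_iri & df$target_iri != onto_b$root_iri
  consistent <- logical(n)
  if (any(resolvable)) {
    tla_map <- top_level_ancestors_map(onto_a, df$source_iri[resolvable])
    tlb_map <- top_level_ancestors_map(onto_b, df$target_iri[resolvable])
    for (i in which(resolvable)) {
      tla <- tla_map[[df$source_iri[[i]]]]
      tlb <- tlb_map[[df$target_iri[[i]]]]
      consistent[[i]] <- any(tlms$pairs$iri_a %in% tla &
                               tlms$pairs$iri_b %in% tlb)
    }
  }
  inconsistent <- resolvable & !consistent
  keys <- pair_key(df$source_iri, df$target_iri)
  discard <- inconsistent & !keys %in% tp_keys

  structure(list(
    pair = c(al$source_ontology_id, al$target_ontology_id),
    consistent = df[resolvable & consistent, , drop = FALSE],
    inconsistent = df[inconsistent, , drop = FALSE],
    unresolvable = df[!resolvable, , drop = FALSE],
    discardable = df[discard, , drop = FALSE],
    inconsistent_count = sum(inconsistent),
    inconsistent_fp_count = sum(discard),
    unresolvable_count = sum(!resolvable),
    proportion_inconsistent = if (n > 0) sum(inconsistent) / n else NA_real_,
    proportion_inconsistent_fp = if (n > 0) sum(discard) / n else NA_real_),
    class = "hierarchy_analysis")
}

#' @export
print.hierarchy_analysis <- function(x, ...) {
  n <- nrow(x$consistent) + nrow(x$inconsistent) + nrow(x$unresolvable)
  cat(sprintf(paste0("hierarchy analysis %s - %s: %d mapping(s), ",
                     "%d inconsistent (%s), of which %d candidate FP (%s)",
                     "%s\n"),
              x$pair[[1]], x$pair[[2]], n,
              x$inconsistent_count,
              if (is.na(x$proportion_inconsistent)) "undefined"
              else format_percent(100 * x$proportion_inconsistent),
              x$inconsistent_fp_count,
              if (is.na(x$proportion_inconsistent_fp)) "undefined"
              else format_percent(100 * x$proportion_inconsistent_fp),
              if (x$unresolvable_count > 0)
                sprintf(", %d unresolvable", x$unresolvable_count) else ""))
  invisible(x)
}

#' Discard hierarchy-inconsistent false positives and re-score
#'
#' Removes from the alignment every mapping that is hierarchy-inconsistent
#' and not a true positive of any of the supplied references (mappings that
#' are TP for at least one reference are kept, even when their top-level
#' hierarchies do not match). Precision and F-measure are then recomputed
#' per reference. Because only false positives of every reference are
#' removed, recall is identical before and after for each reference, and
#' filtered precision is always at least the unfiltered precision.
#'
#' @param al the analyzed, normalized [alignment()].
#' @param analysis the [analyze_alignment()] result for `al`.
#' @param references non-empty list of reference [alignment()]s normalized
#'   to the same pair order as `al`; names are used as reference labels.
#' @return a list with `filtered` (the filtered alignment), `removed`
#'   (data frame of removed mappings), `scores` (one element per reference:
#'   list with `before` and `after` `eval_result`s), and `summary` (data
#'   frame of before/after precision and F-measure with formatted deltas).
#' @export
filter_and_reevaluate <- function(al, analysis, references) {
  stopifnot(inherits(al, "alignment"), inherits(analysis, "hierarchy_analysis"))
  if (!length(references)) stop("at least one reference alignment is required")
  for (ref in references) {
    if (!identical(al$source_ontology_id, ref$source_ontology_id) ||
        !identical(al$target_ontology_id, ref$target_ontology_id)) {
      stop("reference is not normalized to the alignment's pair order")
    }
  }
  labels <- names(references) %||% vapply(references, `[[`, character(1),
                                          "provenance")
  if (is.null(names(references)) || any(!nzchar(labels))) {
    labels <- ifelse(nzchar(labels), labels,
                     paste0("reference", seq_along(references)))
  }

  # Union of TP keys across all references protects mappings from removal.
  keys <- pair_key(al$mappings$source_iri, al$mappings$target_iri)
  tp_keys <- character(0)
  for (ref in references) {
    tp_keys <- c(tp_keys, intersect(keys, alignment_keys(ref)))
  }
  tp_keys <- unique(tp_keys)

  incons_keys <- pair_key(analysis$inconsistent$source_iri,
                          analysis$inconsistent$target_iri)
  remove <- keys %in% setdiff(incons_keys, tp_keys)
  filtered <- alignment(al$source_ontology_id, al$target_ontology_id,
                        al$mappings[!remove, , drop = FALSE],
                        provenance = paste0(al$provenance,
                                            "+hierarchy-filter"))
  scores <- vector("list", length(references))
  names(scores) <- labels
  rows <- vector("list", length(references))
  for (i in seq_along(references)) {
    before <- evaluate_alignment(al, references[[i]],
                                 reference_label = labels[[i]])
    after <- evaluate_alignment(filtered, references[[i]],
                                reference_label = labels[[i]])
    scores[[i]] <- list(before = before, after = after)
    rows[[i]] <- data.frame(
      reference = labels[[i]],
      precision_before = before$precision,
      precision_after = after$precision,
      precision_delta = format_delta(after$precision - before$precision),
      f_before = before$f_measure,
      f_after = after$f_measure,
      f_delta = format_delta(after$f_measure - before$f_measure),
      recall = after$recall,
      stringsAsFactors = FALSE)
  }
  list(filtered = filtered,
       removed = al$mappings[remove, , drop = FALSE],
       scores = scores,
       summary = do.call(rbind, rows))
}
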