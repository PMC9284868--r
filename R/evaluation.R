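#' Construct a CUI annotation table
#'
#' Maps classes of one ontology to their UMLS Concept Unique Identifiers
#' (CUIs). A class may carry several CUIs or none; classes with no CUIs may
#' simply be absent from the map.
#'
#' @param ontology_id short ontology name.
#' @param cui_map named list: class iri to character vector of CUI codes
#'   (`"C"` followed by digits).
#' @return an object of class `cui_table`.
#' @export
cui_table <- function(ontology_id, cui_map) {
  cui_map <- lapply(cui_map, function(v) unique(as.character(v)))
  cui_map <- cui_map[lengths(cui_map) > 0]
  all_cuis <- unlist(cui_map, use.names = FALSE)
  bad <- all_cuis[!grepl("^C[0-9]+$", all_cuis)]
  if (length(bad)) {
    stop("invalid CUI code(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(ontology_id = as.character(ontology_id)[[1]],
                 cui_map = cui_map),
            class = "cui_table")
}

#' Read a CUI annotation table from TSV
#'
#' Columns: `iri`, `cuis` (pipe-separated).
#'
#' @param path path to a TSV file.
#' @param ontology_id short ontology name; defaults to the file name.
#' @return a [cui_table()].
#' @export
read_cui_table <- function(path, ontology_id = NULL) {
  if (!file.exists(path)) stop("CUI table not found: ", path)
  ontology_id <- ontology_id %||% sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          colClasses = "character",
                          na.strings = character(), check.names = FALSE)
  missing <- setdiff(c("iri", "cuis"), names(df))
  if (length(missing)) {
    stop("CUI table is missing column(s): ", paste(missing, collapse = ", "))
  }
  cui_table(ontology_id, stats::setNames(split_pipe(df$cuis), df$iri))
}

#' Write a CUI annotation table to TSV
#'
#' @param table a [cui_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cui_table <- function(table, path) {
  stopifnot(inherits(table, "cui_table"))
  iris <- sort(names(table$cui_map))
  df <- data.frame(iri = iris,
                   cuis = collapse_pipe(lapply(table$cui_map[iris], sort)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Extract a CUI table from an ontology's annotations
#'
#' Some ontologies (e.g. ORDO) ship CUI codes as annotation properties in
#' the ontology file itself rather than via the UMLS; this pulls the
#' per-class CUI sets already loaded on the ontology object.
#'
#' @param ontology an [ontology()].
#' @return a [cui_table()].
#' @export
cui_table_from_ontology <- function(ontology) {
  cui_table(ontology$ontology_id, ontology$cuis)
}

#' Build a CUI-based reference alignment
#'
#' Every pair of classes (one per ontology) sharing at least one CUI becomes
#' an equivalence mapping with confidence 1. Classes carrying several CUIs
#' can induce several mappings (the full cross product over shared CUIs).
#'
#' @param table_a,table_b [cui_table()] objects with distinct ontology ids;
#'   `table_a` provides the mapping sources.
#' @return an [alignment()] with provenance `"cui-reference"`.
#' @export
build_cui_reference <- function(table_a, table_b) {
  stopifnot(inherits(table_a, "cui_table"), inherits(table_b, "cui_table"))
  if (identical(table_a$ontology_id, table_b$ontology_id)) {
    stop("CUI tables must come from distinct ontologies")
  }
  invert <- function(tab) {
    if (!length(tab$cui_map)) return(list())
    iri <- rep(names(tab$cui_map), lengths(tab$cui_map))
    cui <- unlist(tab$cui_map, use.names = FALSE)
    split(iri, cui)
  }
  by_cui_a <- invert(table_a)
  by_cui_b <- invert(table_b)
  shared <- intersect(names(by_cui_a), names(by_cui_b))
  src <- tgt <- character(0)
  for (cc in shared) {
    grid <- expand.grid(a = by_cui_a[[cc]], b = by_cui_b[[cc]],
                        stringsAsFactors = FALSE)
    src <- c(src, grid$a)
    tgt <- c(tgt, grid$b)
  }
  if (length(src)) {
    key <- pair_key(src, tgt)
    keep <- !duplicated(key)
    src <- src[keep]; tgt <- tgt[keep]
  }
  alignment(table_a$ontology_id, table_b$ontology_id,
            sort_mappings(mappings(src, tgt)),
            provenance = "cui-reference")
}

#' Restrict a reference alignment to extracted modules
#'
#' Keeps a mapping only when its source class is present in `module_a` and
#' its target class in `module_b`; used to derive module-scope reference
#' alignments from their full-size counterparts.
#'
#' @param reference an [alignment()] normalized to
#'   (`module_a$ontology_id`, `module_b$ontology_id`).
#' @param module_a,module_b [ontology()] objects (modules).
#' @return the restricted [alignment()].
#' @export
restrict_reference_to_module <- function(reference, module_a, module_b) {
  stopifnot(inherits(reference, "alignment"))
  if (!identical(reference$source_ontology_id, module_a$ontology_id) ||
      !identical(reference$target_ontology_id, module_b$ontology_id)) {
    stop("reference pair order (", reference$source_ontology_id, ", ",
         reference$target_ontology_id,
         ") does not match the module ontologies")
  }
  df <- reference$mappings
  keep <- df$source_iri %in% module_a$iris & df$target_iri %in% module_b$iris
  alignment(reference$source_ontology_id, reference$target_ontology_id,
            df[keep, , drop = FALSE], provenance = reference$provenance)
}

#' Classify mappings as true positive, false positive, or false negative
#'
#' Compares an alignment `A` against a reference alignment `R` over
#' (source, target) mapping identity: true positives are `A` intersect `R`,
#' false positives `A` minus `R`, false negatives `R` minus `A`. The three
#' sets partition the union of `A` and `R`. True negatives are never
#' computed, since no complete gold standard of all correct mappings exists.
#'
#' @param al,reference [alignment()] objects normalized to the same pair
#'   order.
#' @return a list of class `mapping_classification` with data-frame elements
#'   `tp`, `fp`, `fn`.
#' @export
classify_mappings <- function(al, reference) {
  stopifnot(inherits(al, "alignment"), inherits(reference, "alignment"))
  if (!identical(al$source_ontology_id, reference$source_ontology_id) ||
      !identical(al$target_ontology_id, reference$target_ontology_id)) {
    stop("alignment and reference are not normalized to the same pair order")
  }
  a_keys <- alignment_keys(al)
  r_keys <- alignment_keys(reference)
  structure(list(
    tp = al$mappings[a_keys %in% r_keys, , drop = FALSE],
    fp = al$mappings[!a_keys %in% r_keys, , drop = FALSE],
    fn = reference$mappings[!r_keys %in% a_keys, , drop = FALSE]),
    class = "mapping_classification")
}

#' Precision, recall, and F-measure from TP/FP/FN counts
#'
#' Precision = TP / (TP + FP), recall = TP / (TP + FN), F-measure =
#' 2 * precision * recall / (precision + recall). When a denominator is
#' zero the corresponding score is undefined and reported as `NA` -- a
#' distinct marker rather than 0, so that undefined scores cannot silently
#' drag down aggregated means. When precision and recall are both defined
#' and both zero, the F-measure is 0.
#'
#' @param tp,fp,fn non-negative integer counts.
#' @param reference_label free-text label of the reference used.
#' @return an object of class `eval_result` with elements `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f_measure`, `reference_label`.
#' @export
#' @examples
#' score_counts(2, 2, 6) # precision 0.5, recall 0.25, F 1/3
score_counts <- function(tp, fp, fn, reference_label = "") {
  tp <- as.integer(tp); fp <- as.integer(fp); fn <- as.integer(fn)
  if (anyNA(c(tp, fp, fn)) || tp < 0 || fp < 0 || fn < 0) {
    stop("tp, fp, fn must be non-negative counts")
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (is.na(precision) || is.na(recall)) {
    NA_real_
  } else if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f_measure = f,
                 reference_label = as.character(reference_label)[[1]]),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f", round_half_up(v, 2))
  cat(sprintf("evaluation%s: TP=%d FP=%d FN=%d  P=%s R=%s F=%s\n",
              if (nzchar(x$reference_label))
                paste0(" vs ", x$reference_label) else "",
              x$tp, x$fp, x$fn,
              fmt(x$precision), fmt(x$recall), fmt(x$f_measure)))
  invisible(x)
}

#' @export
as.data.frame.eval_result <- function(x, ...) {
  data.frame(reference = x$reference_label, tp = x$tp, fp = x$fp, fn = x$fn,
             precision = x$precision, recall = x$recall,
             f_measure = x$f_measure, stringsAsFactors = FALSE)
}

#' Evaluate an alignment against a reference
#'
#' Convenience wrapper: [classify_mappings()] followed by [score_counts()].
#'
#' @inheritParams classify_mappings
#' @param reference_label label recorded on the result; defaults to the
#'   reference's provenance.
#' @return an `eval_result` (see [score_counts()]).
#' @export
evaluate_alignment <- function(al, reference, reference_label = NULL) {
  cl <- classify_mappings(al, reference)
  score_counts(nrow(cl$tp), nrow(cl$fp), nrow(cl$fn),
               reference_label = reference_label %||% reference$provenance)
}

#' Weighted harmonic mean of the overlap between two reference alignments
#'
#' For reference alignments of sizes `size_a` and `size_b` sharing
#' `intersection` mappings, the overlap proportions are
#' `intersection / size_a` and `intersection / size_b`; their harmonic mean,
#' which weights each reference by its number of mappings, simplifies to
#' `2 * intersection / (size_a + size_b)`.
#'
#' @param size_a,size_b,intersection non-negative counts with
#'   `intersection <= min(size_a, size_b)`.
#' @return the weighted harmonic mean in `[0, 1]`, or `NA` when both sizes
#'   are zero.
#' @export
#' @examples
#' harmonic_overlap(3861, 1750, 776) # ~0.277
harmonic_overlap <- function(size_a, size_b, intersection) {
  if (any(c(size_a, size_b, intersection) < 0)) {
    stop("sizes and intersection must be non-negative")
  }
  if (intersection > min(size_a, size_b)) {
    stop("intersection cannot exceed the smaller reference size")
  }
  if (size_a + size_b == 0) return(NA_real_)
  2 * intersection / (size_a + size_b)
}

#' Overlap statistics between two reference alignments
#'
#' @param ref_a,ref_b [alignment()] objects normalized to the same pair
#'   order.
#' @return an object of class `overlap_stats` with sizes, intersection
#'   count, per-reference overlap proportions, the weighted harmonic mean
#'   (symmetric in the two references), and percentage labels.
#' @export
overlap_stats <- function(ref_a, ref_b) {
  stopifnot(inherits(ref_a, "alignment"), inherits(ref_b, "alignment"))
  if (!identical(ref_a$source_ontology_id, ref_b$source_ontology_id) ||
      !identical(ref_a$target_ontology_id, ref_b$target_ontology_id)) {
    stop("reference alignments are not normalized to the same pair order")
  }
  ka <- unique(alignment_keys(ref_a))
  kb <- unique(alignment_keys(ref_b))
  size_a <- length(ka); size_b <- length(kb)
  inter <- length(intersect(ka, kb))
  whm <- harmonic_overlap(size_a, size_b, inter)
  structure(list(
    size_a = size_a, size_b = size_b, intersection = inter,
    proportion_a = if (size_a > 0) inter / size_a else NA_real_,
    proportion_b = if (size_b > 0) inter / size_b else NA_real_,
    weighted_harmonic_mean = whm,
    pct_label = format_percent(100 * whm)),
    class = "overlap_stats")
}

#' @export
print.overlap_stats <- function(x, ...) {
  cat(sprintf("overlap: |A|=%d |B|=%d intersection=%d harmonic mean=%s\n",
              x$size_a, x$size_b, x$intersection,
              if (is.na(x$weighted_harmonic_mean)) "undefined"
              else x$pct_label))
  invisible(x)
}

#' Mean scores across evaluation results
#'
#' Arithmetic mean of precision, recall, and F-measure per group (e.g. the
#' mean over all matching systems for one ontology pair). Undefined scores
#' (`NA`) are excluded from the mean, with a message reporting how many were
#' dropped; mean-of-scores is used, not scores of pooled counts.
#'
#' @param results either a data frame with columns `precision`, `recall`,
#'   `f_measure` (plus any grouping columns) or a list of `eval_result`
#'   objects.
#' @param group_by optional character vector of column names to group by;
#'   `NULL` averages over everything.
#' @return a data frame of group means with a column `n` (results per
#'   group).
#' @export
aggregate_means <- function(results, group_by = NULL) {
  if (is.data.frame(results)) {
    df <- results
  } else if (is.list(results) && length(results) &&
             all(vapply(results, inherits, logical(1), "eval_result"))) {
    df <- do.call(rbind, lapply(results, as.data.frame))
  } else {
    stop("`results` must be a non-empty list of eval_result objects ",
         "or a data frame")
  }
  if (!nrow(df)) stop("no evaluation results to aggregate")
  score_cols <- intersect(c("precision", "recall", "f_measure"), names(df))
  if (!length(score_cols)) stop("no score columns found")
  n_undef <- sum(is.na(df[score_cols]))
  if (n_undef > 0) {
    message("aggregate_means: excluding ", n_undef, " undefined score(s)")
  }
  if (is.null(group_by)) {
    out <- as.data.frame(lapply(df[score_cols], mean, na.rm = TRUE))
    out$n <- nrow(df)
    return(out)
  }
  missing <- setdiff(group_by, names(df))
  if (length(missing)) {
    stop("grouping column(s) not found: ", paste(missing, collapse = ", "))
  }
  agg <- stats::aggregate(df[score_cols], by = df[group_by],
                          FUN = mean, na.rm = TRUE)
  counts <- stats::aggregate(stats::setNames(list(rep(1L, nrow(df))), "n"),
                             by = df[group_by], FUN = sum)
  merge(agg, counts, by = group_by, sort = TRUE)
}
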