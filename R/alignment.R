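MAPPING_RELATIONS <- c("equivalence", "subsumes", "subsumed_by",
                       "more_generic", "more_specific")

#' Construct a mappings table
#'
#' A mapping is a correspondence between one class of a source ontology and
#' one class of a target ontology, with a relation and an optional
#' confidence. Mappings are stored as rows of a data frame; extra columns
#' (e.g. provenance labels for planted synthetic mappings) are carried along
#' but play no role in mapping identity.
#'
#' @param source_iri,target_iri character vectors of class identifiers.
#' @param relation mapping relation; one of `"equivalence"`, `"subsumes"`,
#'   `"subsumed_by"`, `"more_generic"`, `"more_specific"`.
#' @param confidence numeric in `[0, 1]`.
#' @return data frame with columns `source_iri`, `target_iri`, `relation`,
#'   `confidence`.
#' @export
mappings <- function(source_iri = character(), target_iri = character(),
                     relation = "equivalence", confidence = 1) {
  data.frame(source_iri = as.character(source_iri),
             target_iri = as.character(target_iri),
             relation = rep_len(as.character(relation),
                                length(source_iri)),
             confidence = rep_len(as.numeric(confidence),
                                  length(source_iri)),
             stringsAsFactors = FALSE)
}

#' Construct an alignment
#'
#' An alignment is the set of mappings produced (by a matching system, a
#' reference extraction, or a consensus vote) between one ordered pair of
#' ontologies. No two mappings may share the same (source, target, relation)
#' triple; mapping identity ignores confidence.
#'
#' @param source_ontology_id,target_ontology_id distinct short ontology
#'   names.
#' @param mappings a data frame as returned by [mappings()].
#' @param provenance free-text label, e.g. the matcher name.
#' @return an object of class `alignment`.
#' @seealso [read_alignment_rdf()], [normalize_alignment()],
#'   [consensus_alignment()]
#' @export
alignment <- function(source_ontology_id, target_ontology_id,
                      mappings = ontalign::mappings(),
                      provenance = "") {
  source_ontology_id <- as.character(source_ontology_id)[[1]]
  target_ontology_id <- as.character(target_ontology_id)[[1]]
  if (!nzchar(source_ontology_id) || !nzchar(target_ontology_id)) {
    stop("ontology ids must be non-empty")
  }
  if (identical(source_ontology_id, target_ontology_id)) {
    stop("source and target ontology ids must differ")
  }
  needed <- c("source_iri", "target_iri", "relation", "confidence")
  missing <- setdiff(needed, names(mappings))
  if (length(missing)) {
    stop("mappings table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(mappings)) {
    if (any(!nzchar(mappings$source_iri)) || any(!nzchar(mappings$target_iri))) {
      stop("mapping entity iris must be non-empty")
    }
    bad_rel <- setdiff(unique(mappings$relation), MAPPING_RELATIONS)
    if (length(bad_rel)) {
      stop("unknown mapping relation(s): ", paste(bad_rel, collapse = ", "))
    }
    if (any(mappings$confidence < 0 | mappings$confidence > 1)) {
      stop("mapping confidence must lie in [0, 1]")
    }
    key <- paste(mappings$source_iri, mappings$target_iri,
                 mappings$relation, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate mapping (same source, target, and relation)")
    }
  }
  rownames(mappings) <- NULL
  structure(list(source_ontology_id = source_ontology_id,
                 target_ontology_id = target_ontology_id,
                 mappings = mappings,
                 provenance = as.character(provenance)[[1]]),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment %s -> %s: %d mapping(s)%s\n",
              x$source_ontology_id, x$target_ontology_id,
              nrow(x$mappings),
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]")
              else ""))
  invisible(x)
}

alignment_keys <- function(al) {
  pair_key(al$mappings$source_iri, al$mappings$target_iri)
}

sort_mappings <- function(df) {
  if (!nrow(df)) return(df)
  df <- df[order(df$source_iri, df$target_iri, df$relation), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Normalize an alignment to a fixed pair order
#'
#' Matching A to B is equivalent to matching B to A, so alignments over the
#' same ontology pair may arrive in either orientation. Normalization
#' reorients all mappings so the source belongs to `pair_order[1]`, drops
#' non-equivalence mappings (with a message stating how many), collapses
#' duplicates keeping the maximum confidence, and sorts mappings. The
#' operation is idempotent.
#'
#' @param al an [alignment()].
#' @param pair_order length-2 character vector of ontology ids; must equal
#'   the alignment's two ids as a set.
#' @return a normalized [alignment()].
#' @export
normalize_alignment <- function(al, pair_order) {
  stopifnot(inherits(al, "alignment"))
  pair_order <- as.character(pair_order)
  if (length(pair_order) != 2 ||
      !setequal(pair_order,
                c(al$source_ontology_id, al$target_ontology_id))) {
    stop("pair order (", paste(pair_order, collapse = ", "),
         ") does not match alignment ontologies (",
         al$source_ontology_id, ", ", al$target_ontology_id, ")")
  }
  df <- al$mappings
  if (!identical(al$source_ontology_id, pair_order[[1]])) {
    tmp <- df$source_iri
    df$source_iri <- df$target_iri
    df$target_iri <- tmp
    # equivalence is symmetric; directed relations flip under reorientation
    flip <- c(equivalence = "equivalence",
              subsumes = "subsumed_by", subsumed_by = "subsumes",
              more_generic = "more_specific",
              more_specific = "more_generic")
    df$relation <- unname(flip[df$relation])
  }
  non_eq <- sum(df$relation != "equivalence")
  if (non_eq > 0) {
    message("normalize_alignment: dropping ", non_eq,
            " non-equivalence mapping(s)")
    df <- df[df$relation == "equivalence", , drop = FALSE]
  }
  if (nrow(df)) {
    key <- pair_key(df$source_iri, df$target_iri)
    if (anyDuplicated(key)) {
      best <- tapply(df$confidence, key, max)
      df <- df[!duplicated(key), , drop = FALSE]
      df$confidence <- unname(best[pair_key(df$source_iri, df$target_iri)])
    }
  }
  alignment(pair_order[[1]], pair_order[[2]], sort_mappings(df),
            provenance = al$provenance)
}

#' Vote-based consensus of several alignments
#'
#' Builds the consensus alignment containing every equivalence mapping that
#' occurs in at least `min_votes` of the input alignments. Mapping identity
#' is the (source, target) class pair; confidences of the inputs are
#' ignored, and the consensus confidence is the vote fraction
#' (votes / number of alignments). All inputs must be normalized to the same
#' pair order.
#'
#' @param alignments non-empty list of normalized [alignment()] objects over
#'   the same ordered ontology pair.
#' @param min_votes integer between 1 and `length(alignments)`. `min_votes
#'   = 1` yields the union of the inputs.
#' @return an [alignment()] whose provenance records the vote threshold.
#' @export
consensus_alignment <- function(alignments, min_votes) {
  if (!length(alignments)) stop("empty alignment list")
  if (!all(vapply(alignments, inherits, logical(1), "alignment"))) {
    stop("all inputs must be alignment objects")
  }
  n <- length(alignments)
  min_votes <- as.integer(min_votes)
  if (is.na(min_votes) || min_votes < 1 || min_votes > n) {
    stop("min_votes must lie between 1 and the number of alignments (", n, ")")
  }
  src <- unique(vapply(alignments, `[[`, character(1), "source_ontology_id"))
  tgt <- unique(vapply(alignments, `[[`, character(1), "target_ontology_id"))
  if (length(src) != 1 || length(tgt) != 1) {
    stop("alignments are not normalized to the same pair order")
  }
  per <- lapply(alignments, function(a) {
    df <- a$mappings[a$mappings$relation == "equivalence",
                     c("source_iri", "target_iri"), drop = FALSE]
    df[!duplicated(pair_key(df$source_iri, df$target_iri)), , drop = FALSE]
  })
  all_pairs <- do.call(rbind, per)
  if (!nrow(all_pairs)) {
    return(alignment(src, tgt, mappings(),
                     provenance = sprintf("consensus(vote>=%d/%d)",
                                          min_votes, n)))
  }
  key <- pair_key(all_pairs$source_iri, all_pairs$target_iri)
  votes <- table(key)
  keep_keys <- names(votes)[votes >= min_votes]
  sel <- all_pairs[!duplicated(key) & key %in% keep_keys, , drop = FALSE]
  sel_votes <- as.integer(votes[pair_key(sel$source_iri, sel$target_iri)])
  out <- mappings(sel$source_iri, sel$target_iri,
                  relation = "equivalence",
                  confidence = sel_votes / n)
  alignment(src, tgt, sort_mappings(out),
            provenance = sprintf("consensus(vote>=%d/%d)", min_votes, n))
}
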