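#' Extend a seed signature with all ancestors
#'
#' A seed signature is the list of classes a module is extracted around.
#' Extending the seed with every ancestor of every seed class guarantees
#' that the extracted module contains the full top-level hierarchy above the
#' seed, which keeps category (top-level ancestor) queries well defined
#' inside the module. The operation is a closure: applying it twice gives
#' the same result, and the root is always contained in the output.
#'
#' @param ontology an [ontology()] object.
#' @param seed_iris non-empty character vector of class iris present in the
#'   ontology.
#' @return sorted character vector: the seed plus all its ancestors.
#' @export
extend_seed_with_ancestors <- function(ontology, seed_iris) {
  seed_iris <- unique(as.character(seed_iris))
  if (!length(seed_iris)) stop("seed signature must be non-empty")
  missing <- setdiff(seed_iris, ontology$iris)
  if (length(missing)) {
    stop("seed class(es) not in ontology '", ontology$ontology_id, "': ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  out <- seed_iris
  for (iri in seed_iris) out <- c(out, ancestors(ontology, iri))
  sort(unique(out))
}

#' Extract a top, bottom, or star module
#'
#' Extracts a subset of the ontology around a seed signature, following the
#' hierarchy semantics of locality-style module extraction over the
#' subclass DAG:
#' \describe{
#'   \item{top}{the seed plus all descendants of seed classes,}
#'   \item{bottom}{the seed plus all ancestors of seed classes,}
#'   \item{star}{the intersection of the top- and bottom-module class sets.}
#' }
#' The seed is contained in the module in every mode, and the root is always
#' retained. Parent edges are kept only between retained classes; a retained
#' non-root class whose parents were all dropped is re-attached directly to
#' the root, so the module is itself a valid rooted ontology.
#'
#' @inheritParams extend_seed_with_ancestors
#' @param mode one of `"star"`, `"top"`, `"bottom"`.
#' @return an [ontology()] object restricted to the module's classes.
#' @export
#' @examples
#' ont <- ontology("TOY", c("root", "a", "b", "c"),
#'                 list(root = character(), a = "root", b = "a", c = "b"))
#' extract_module(ont, "b", "star")$iris
extract_module <- function(ontology, seed_iris,
                           mode = c("star", "top", "bottom")) {
  mode <- match.arg(mode)
  seed_iris <- unique(as.character(seed_iris))
  if (!length(seed_iris)) stop("seed signature must be non-empty")
  missing <- setdiff(seed_iris, ontology$iris)
  if (length(missing)) {
    stop("seed class(es) not in ontology '", ontology$ontology_id, "': ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  down <- seed_iris
  up <- seed_iris
  if (mode %in% c("top", "star")) {
    for (iri in seed_iris) down <- c(down, descendants(ontology, iri))
    down <- unique(down)
  }
  if (mode %in% c("bottom", "star")) {
    for (iri in seed_iris) up <- c(up, ancestors(ontology, iri))
    up <- unique(up)
  }
  keep <- switch(mode, top = down, bottom = up, star = intersect(down, up))
  keep <- unique(c(keep, ontology$root_iri))

  parents <- lapply(ontology$parents[keep],
                    function(p) p[p %in% keep])
  names(parents) <- keep
  orphaned <- keep[lengths(parents) == 0 & keep != ontology$root_iri]
  for (iri in orphaned) parents[[iri]] <- ontology$root_iri

  ontology(ontology$ontology_id, keep, parents,
           labels = ontology$labels[keep],
           synonyms = ontology$synonyms[keep],
           cuis = ontology$cuis[keep])
}

#' Summarize module size relative to its parent ontology
#'
#' @param ontology the full [ontology()].
#' @param module a module extracted from it; its classes must be a subset of
#'   the full ontology's classes.
#' @return a list with `n_module`, `n_total`, `pct` (raw percentage), and
#'   `pct_label` (nearest integer, one decimal below 1 percent).
#' @export
#' @examples
#' # 299 of 14,502 classes retained
#' module_stats_counts(299, 14502)$pct_label
module_stats <- function(ontology, module) {
  extra <- setdiff(module$iris, ontology$iris)
  if (length(extra)) {
    stop("module contains class(es) not in the ontology: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  module_stats_counts(length(module$iris), length(ontology$iris))
}

#' @rdname module_stats
#' @param n_module,n_total class counts.
#' @export
module_stats_counts <- function(n_module, n_total) {
  if (n_total < 1 || n_module < 0 || n_module > n_total) {
    stop("invalid module/ontology class counts")
  }
  pct <- 100 * n_module / n_total
  list(n_module = as.integer(n_module), n_total = as.integer(n_total),
       pct = pct, pct_label = format_percent(pct))
}
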