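#' Construct an ontology object
#'
#' An `ontology` is a lightweight representation of a class hierarchy: a
#' rooted directed acyclic graph (DAG) of named classes connected by
#' subclass-of (child to parent) edges, where each class may carry a
#' preferred label, synonyms, and UMLS Concept Unique Identifier (CUI)
#' annotations. Multiple inheritance is allowed; the graph must be acyclic,
#' have exactly one parentless class (the root), and every class must reach
#' the root through parent edges.
#'
#' @param ontology_id short name for the ontology (e.g. `"ORDO"`).
#' @param iris character vector of unique, non-empty class identifiers.
#' @param parents named list (one element per class, names matching `iris`)
#'   of character vectors of parent identifiers. Exactly one class (the
#'   root) has no parents.
#' @param labels optional named character vector of preferred labels.
#' @param synonyms optional named list of character vectors of synonyms.
#' @param cuis optional named list of character vectors of CUI codes
#'   (`"C"` followed by digits).
#' @return an object of class `ontology` with elements `ontology_id`,
#'   `root_iri`, `iris`, `parents`, `children`, `labels`, `synonyms`,
#'   and `cuis`.
#' @seealso [load_ontology_tsv()], [load_ontology_owl()], [ancestors()],
#'   [descendants()], [top_level_classes()]
#' @export
#' @examples
#' ont <- ontology("TOY", c("root", "a", "b"),
#'                 list(root = character(), a = "root", b = "a"))
#' top_level_classes(ont)
ontology <- function(ontology_id, iris, parents,
                     labels = NULL, synonyms = NULL, cuis = NULL) {
  iris <- as.character(iris)
  if (length(iris) < 1) stop("ontology must contain at least one class")
  if (any(!nzchar(iris)) || anyNA(iris)) stop("class iris must be non-empty")
  dup <- iris[duplicated(iris)]
  if (length(dup)) {
    stop("duplicate class iri(s): ", paste(unique(dup), collapse = ", "))
  }

  parents <- lapply(parents, function(p) unique(as.character(p)))
  if (is.null(names(parents)) || !setequal(names(parents), iris)) {
    stop("`parents` must be a named list covering exactly the class iris")
  }
  parents <- parents[iris]

  unknown <- setdiff(unlist(parents, use.names = FALSE), iris)
  if (length(unknown)) {
    stop("parent iri(s) not declared as classes: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  self_par <- iris[mapply(function(i, p) i %in% p, iris, parents)]
  if (length(self_par)) {
    stop("class is its own parent: ", self_par[[1]])
  }

  n_par <- lengths(parents)
  roots <- iris[n_par == 0]
  if (length(roots) == 0) {
    stop("no root class found: every class has a parent (cycle?)")
  }
  if (length(roots) > 1) {
    stop("multiple parentless classes: ",
         paste(utils::head(roots, 5), collapse = ", "),
         " (exactly one root is required)")
  }
  root_iri <- roots[[1]]

  # Kahn's algorithm over child -> parent edges; leftover nodes lie on a
  # cycle, in which case one member is named in the error.
  children <- children_index(iris, parents)
  indeg <- lengths(parents)
  names(indeg) <- iris
  queue <- root_iri
  seen <- 0L
  while (length(queue)) {
    node <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (ch in children[[node]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(iris)) {
    cyc <- iris[indeg[iris] > 0L]
    stop("cycle in subclass graph involving class: ", cyc[[1]])
  }

  labels <- normalize_annotation(labels, iris, default = "")
  synonyms <- normalize_annotation_list(synonyms, iris)
  cuis <- normalize_annotation_list(cuis, iris)

  structure(
    list(ontology_id = as.character(ontology_id)[[1]],
         root_iri = root_iri,
         iris = iris,
         parents = parents,
         children = children,
         labels = labels,
         synonyms = synonyms,
         cuis = cuis),
    class = "ontology")
}

children_index <- function(iris, parents) {
  children <- stats::setNames(vector("list", length(iris)), iris)
  for (i in seq_along(iris)) children[[i]] <- character(0)
  child_of <- rep(iris, lengths(parents))
  par <- unlist(parents, use.names = FALSE)
  if (length(par)) {
    sp <- split(child_of, par)
    children[names(sp)] <- sp
  }
  children
}

normalize_annotation <- function(x, iris, default) {
  out <- stats::setNames(rep(default, length(iris)), iris)
  if (!is.null(x)) {
    x <- x[!is.na(x)]
    keep <- intersect(names(x), iris)
    out[keep] <- as.character(x[keep])
  }
  out
}

normalize_annotation_list <- function(x, iris) {
  out <- stats::setNames(vector("list", length(iris)), iris)
  for (i in seq_along(out)) out[[i]] <- character(0)
  if (!is.null(x)) {
    keep <- intersect(names(x), iris)
    out[keep] <- lapply(x[keep], function(v) unique(as.character(v)))
  }
  out
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("ontology '%s': %d classes, root <%s>, %d top-level classes\n",
              x$ontology_id, length(x$iris), x$root_iri,
              length(top_level_classes(x))))
  invisible(x)
}

stop_unknown_iri <- function(ontology, iri) {
  if (length(iri) != 1 || is.na(iri) || !iri %in% ontology$iris) {
    stop("unknown class iri: ", iri, " (ontology '",
         ontology$ontology_id, "')")
  }
}

#' Strict ancestors of a class
#'
#' All classes reachable from `iri` by following parent (subclass-of) edges,
#' excluding `iri` itself. The transitive closure is taken over the DAG, so
#' multiple-inheritance paths are all followed; the root is always among the
#' ancestors of a non-root class.
#'
#' @param ontology an [ontology()] object.
#' @param iri class identifier present in the ontology.
#' @return character vector of ancestor iris (unordered set).
#' @export
ancestors <- function(ontology, iri) {
  stop_unknown_iri(ontology, iri)
  seen <- character(0)
  frontier <- ontology$parents[[iri]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    if (!length(new)) break
    seen <- c(seen, new)
    frontier <- unique(unlist(ontology$parents[new], use.names = FALSE))
  }
  seen
}

#' Strict descendants of a class
#'
#' All classes reachable from `iri` by following child edges (the reverse of
#' parent edges), excluding `iri` itself.
#'
#' @inheritParams ancestors
#' @return character vector of descendant iris (unordered set).
#' @export
descendants <- function(ontology, iri) {
  stop_unknown_iri(ontology, iri)
  seen <- character(0)
  frontier <- ontology$children[[iri]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    if (!length(new)) break
    seen <- c(seen, new)
    frontier <- unique(unlist(ontology$children[new], use.names = FALSE))
  }
  seen
}

#' Top-level classes of an ontology
#'
#' The top-level classes are the direct children of the root; they act as the
#' broad semantic categories of the ontology (e.g. the 19 top-level classes
#' of SNOMED CT such as Clinical finding or Body structure).
#'
#' @inheritParams ancestors
#' @return character vector of top-level class iris.
#' @export
top_level_classes <- function(ontology) {
  sort(ontology$children[[ontology$root_iri]])
}

#' Top-level ancestors of a class
#'
#' The categories a class belongs to: the intersection of the class itself
#' plus its strict ancestors with the top-level classes. A top-level class is
#' its own (sole) top-level ancestor; a non-root class in a valid ontology
#' always has at least one. The root has none, which is an error.
#'
#' @inheritParams ancestors
#' @return character vector of top-level class iris (at least one).
#' @export
top_level_ancestors <- function(ontology, iri) {
  stop_unknown_iri(ontology, iri)
  if (identical(iri, ontology$root_iri)) {
    stop("the root class has no top-level ancestor")
  }
  sort(intersect(c(iri, ancestors(ontology, iri)),
                 top_level_classes(ontology)))
}

# Internal: top-level ancestors for many classes at once, memoised.
top_level_ancestors_map <- function(ontology, iris) {
  iris <- unique(iris)
  tls <- top_level_classes(ontology)
  out <- stats::setNames(vector("list", length(iris)), iris)
  for (iri in iris) {
    out[[iri]] <- sort(intersect(c(iri, ancestors(ontology, iri)), tls))
  }
  out
}
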