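#' Read an ontology from the TSV hierarchy format
#'
#' The TSV dialect has a mandatory header row and columns `iri`,
#' `parent_iris`, `label`, `synonyms`, `cuis`; multi-valued cells are
#' pipe-separated. Exactly one row must have an empty `parent_iris` cell:
#' that class is the root.
#'
#' @param path path to a UTF-8 TSV file.
#' @param ontology_id short name for the ontology; defaults to the file name
#'   without extension.
#' @return an [ontology()] object.
#' @export
load_ontology_tsv <- function(path, ontology_id = NULL) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  ontology_id <- ontology_id %||%
    sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, sep = "\t", quote = "",
                          colClasses = "character",
                          na.strings = character(),
                          check.names = FALSE, encoding = "UTF-8")
  needed <- c("iri", "parent_iris", "label", "synonyms", "cuis")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("ontology TSV is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$iri)) {
    stop("duplicate class iri in ontology TSV: ",
         df$iri[duplicated(df$iri)][[1]])
  }
  parents <- stats::setNames(split_pipe(df$parent_iris), df$iri)
  n_roots <- sum(lengths(parents) == 0)
  if (n_roots == 0) stop("ontology TSV has no root row (empty parent_iris)")
  if (n_roots > 1) {
    stop("ontology TSV has ", n_roots,
         " parentless rows; exactly one root is required")
  }
  ontology(ontology_id, df$iri, parents,
           labels = stats::setNames(df$label, df$iri),
           synonyms = stats::setNames(split_pipe(df$synonyms), df$iri),
           cuis = stats::setNames(split_pipe(df$cuis), df$iri))
}

#' Write an ontology to the TSV hierarchy format
#'
#' Inverse of [load_ontology_tsv()]. Rows are sorted by iri so output is
#' deterministic; multi-valued cells are pipe-separated and are themselves
#' written in sorted order.
#'
#' @param ontology an [ontology()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ontology_tsv <- function(ontology, path) {
  iris <- sort(ontology$iris)
  df <- data.frame(
    iri = iris,
    parent_iris = collapse_pipe(lapply(ontology$parents[iris], sort)),
    label = unname(ontology$labels[iris]),
    synonyms = collapse_pipe(lapply(ontology$synonyms[iris], sort)),
    cuis = collapse_pipe(lapply(ontology$cuis[iris], sort)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Default annotation-property identifiers. CUIs are commonly exposed with
# the BioPortal UMLS property; synonyms via skos:altLabel or the oboInOwl
# exact-synonym dialect.
DEFAULT_CUI_PROPERTIES <- c(
  "http://purl.bioontology.org/ontology/UMLS/cui",
  "http://bioportal.bioontology.org/ontologies/umls/cui")

DEFAULT_SYNONYM_PROPERTIES <- c(
  "http://www.w3.org/2004/02/skos/core#altLabel",
  "http://www.geneontology.org/formats/oboInOwl#hasExactSynonym",
  "http://www.geneontology.org/formats/oboInOwl#hasRelatedSynonym")

RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS <- "http://www.w3.org/2002/07/owl#"

split_iri <- function(iri) {
  pos <- regexpr("[#/][^#/]*$", iri)
  if (pos < 0) stop("cannot split property iri into namespace and local name: ", iri)
  c(substr(iri, 1, pos), substr(iri, pos + 1, nchar(iri)))
}

ns_prefixes_for <- function(ns_map, uri) {
  names(ns_map)[ns_map == uri]
}

#' Read an ontology from OWL (RDF/XML)
#'
#' Reads the named-class fragment of an OWL file serialized as RDF/XML:
#' `owl:Class` elements with an `rdf:about` identifier, subclass edges from
#' `rdfs:subClassOf` elements that point at a named class via
#' `rdf:resource`, preferred labels from `rdfs:label`, synonyms and CUI
#' codes from configurable annotation properties. Anonymous and complex
#' class expressions (restrictions, intersections, ...) are ignored.
#'
#' Classes referenced as parents but not themselves declared are added
#' implicitly. If the file contains exactly one parentless class it becomes
#' the root; otherwise a synthetic root is created and all parentless
#' classes are attached to it, so that every class has a well-defined set of
#' top-level ancestors.
#'
#' @param path path to an RDF/XML file.
#' @param ontology_id short name for the ontology; defaults to the file name
#'   without extension.
#' @param cui_property_iris character vector of annotation-property IRIs
#'   whose values are CUI codes.
#' @param synonym_property_iris character vector of annotation-property IRIs
#'   whose values are synonyms.
#' @return an [ontology()] object.
#' @export
load_ontology_owl <- function(path, ontology_id = NULL,
                              cui_property_iris = DEFAULT_CUI_PROPERTIES,
                              synonym_property_iris = DEFAULT_SYNONYM_PROPERTIES) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  ontology_id <- ontology_id %||% sub("\\.[^.]*$", "", basename(path))
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    stop("cannot parse RDF/XML file '", path, "': ",
                         conditionMessage(e))
                  })
  ns <- xml2::xml_ns(doc)
  rdf_p <- ns_prefixes_for(ns, RDF_NS)
  if (!length(rdf_p)) stop("file does not declare the RDF namespace: ", path)
  rdf_p <- rdf_p[[1]]
  owl_p <- ns_prefixes_for(ns, OWL_NS)
  if (!length(owl_p)) stop("file does not declare the OWL namespace: ", path)
  owl_p <- owl_p[[1]]
  rdfs_p <- ns_prefixes_for(ns, RDFS_NS)

  about_attr <- paste0(rdf_p, ":about")
  resource_attr <- paste0(rdf_p, ":resource")
  class_nodes <- xml2::xml_find_all(
    doc, sprintf(".//%s:Class[@%s]", owl_p, about_attr), ns)

  iris <- xml2::xml_attr(class_nodes, "about")
  # A class may be serialized in several blocks; merge by iri.
  parents <- list(); labels <- character(0)
  synonyms <- list(); cuis <- list()
  prop_values <- function(node, prop_iris) {
    vals <- character(0)
    for (p in prop_iris) {
      parts <- split_iri(p)
      for (pre in ns_prefixes_for(ns, parts[[1]])) {
        hits <- xml2::xml_find_all(node, sprintf("./%s:%s", pre, parts[[2]]), ns)
        vals <- c(vals, xml2::xml_text(hits))
      }
    }
    unique(vals[nzchar(vals)])
  }
  for (k in seq_along(class_nodes)) {
    iri <- iris[[k]]
    node <- class_nodes[[k]]
    par <- character(0)
    if (length(rdfs_p)) {
      sub_nodes <- xml2::xml_find_all(
        node, sprintf("./%s:subClassOf[@%s]", rdfs_p[[1]], resource_attr), ns)
      par <- xml2::xml_attr(sub_nodes, "resource")
      lab <- xml2::xml_text(xml2::xml_find_all(
        node, sprintf("./%s:label", rdfs_p[[1]]), ns))
    } else {
      lab <- character(0)
    }
    parents[[iri]] <- unique(c(parents[[iri]], par))
    if (length(lab)) {
      cur <- if (iri %in% names(labels)) labels[[iri]] else ""
      if (!nzchar(cur)) labels[iri] <- lab[[1]]
    }
    synonyms[[iri]] <- unique(c(synonyms[[iri]],
                                prop_values(node, synonym_property_iris)))
    cuis[[iri]] <- unique(c(cuis[[iri]], prop_values(node, cui_property_iris)))
  }

  all_iris <- unique(c(names(parents), unlist(parents, use.names = FALSE)))
  for (iri in setdiff(all_iris, names(parents))) parents[[iri]] <- character(0)
  parents <- lapply(parents, function(p) p[p %in% all_iris])

  parentless <- names(parents)[lengths(parents) == 0]
  if (length(parentless) > 1) {
    root <- paste0("urn:ontalign:", ontology_id, ":root")
    parents[[root]] <- character(0)
    for (iri in parentless) parents[[iri]] <- root
    labels[root] <- "Thing"
    all_iris <- c(all_iris, root)
  }

  out <- tryCatch(
    ontology(ontology_id, names(parents), parents,
             labels = labels, synonyms = synonyms, cuis = cuis),
    error = function(e) {
      stop("invalid class hierarchy in '", path, "': ", conditionMessage(e))
    })
  out
}

#' Write an ontology to OWL (RDF/XML)
#'
#' Emits the named-class dialect read back by [load_ontology_owl()]: one
#' `owl:Class` per class with `rdfs:label`, `skos:altLabel` synonyms, CUI
#' annotations, and `rdfs:subClassOf` edges. Output is deterministic
#' (classes and multi-values sorted).
#'
#' @param ontology an [ontology()] object.
#' @param path output file path.
#' @param cui_property_iri annotation-property IRI used for CUI codes.
#' @param synonym_property_iri annotation-property IRI used for synonyms.
#' @return `path`, invisibly.
#' @export
write_ontology_owl <- function(ontology, path,
                               cui_property_iri = DEFAULT_CUI_PROPERTIES[[1]],
                               synonym_property_iri = DEFAULT_SYNONYM_PROPERTIES[[1]]) {
  cui_parts <- split_iri(cui_property_iri)
  syn_parts <- split_iri(synonym_property_iri)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<rdf:RDF xmlns:rdf=\"%s\" xmlns:rdfs=\"%s\" ",
                   "xmlns:owl=\"%s\" xmlns:syn=\"%s\" xmlns:cui=\"%s\">"),
            RDF_NS, RDFS_NS, OWL_NS,
            esc(syn_parts[[1]]), esc(cui_parts[[1]])),
    sprintf("  <owl:Ontology rdf:about=\"urn:ontalign:%s\"/>",
            esc(ontology$ontology_id)))
  for (iri in sort(ontology$iris)) {
    lines <- c(lines, sprintf("  <owl:Class rdf:about=\"%s\">", esc(iri)))
    if (nzchar(ontology$labels[[iri]])) {
      lines <- c(lines, sprintf("    <rdfs:label>%s</rdfs:label>",
                                esc(ontology$labels[[iri]])))
    }
    for (s in sort(ontology$synonyms[[iri]])) {
      lines <- c(lines, sprintf("    <syn:%s>%s</syn:%s>",
                                syn_parts[[2]], esc(s), syn_parts[[2]]))
    }
    for (cc in sort(ontology$cuis[[iri]])) {
      lines <- c(lines, sprintf("    <cui:%s>%s</cui:%s>",
                                cui_parts[[2]], esc(cc), cui_parts[[2]]))
    }
    for (p in sort(ontology$parents[[iri]])) {
      lines <- c(lines, sprintf("    <rdfs:subClassOf rdf:resource=\"%s\"/>",
                                esc(p)))
    }
    lines <- c(lines, "  </owl:Class>")
  }
  lines <- c(lines, "</rdf:RDF>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
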