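ALIGN_NS <- "http://knowledgeweb.semanticweb.org/heterogeneity/alignment"

RELATION_TO_SYMBOL <- c(equivalence = "=",
                        subsumes = ">", subsumed_by = "<",
                        more_generic = ">=", more_specific = "<=")
SYMBOL_TO_RELATION <- stats::setNames(names(RELATION_TO_SYMBOL),
                                      RELATION_TO_SYMBOL)

#' Read an alignment from the Alignment API RDF format
#'
#' Parses the general exchange format used by ontology matching systems:
#' an `Alignment` element (knowledgeweb heterogeneity/alignment namespace)
#' containing `Cell` elements with `entity1`, `entity2`, `relation`, and
#' `measure`. The relation symbol `"="` maps to equivalence, `"<"`/`">"` to
#' subsumed-by/subsumes, `"<="`/`">="` to more-specific/more-generic; the
#' measure becomes the mapping confidence (1 when absent).
#'
#' @param path path to an Alignment API RDF/XML file.
#' @param source_ontology_id,target_ontology_id optional ontology ids
#'   overriding the `onto1`/`onto2` declarations in the file.
#' @param provenance optional provenance label; defaults to the file name.
#' @return an [alignment()].
#' @export
read_alignment_rdf <- function(path, source_ontology_id = NULL,
                               target_ontology_id = NULL,
                               provenance = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    stop("cannot parse alignment RDF file '", path, "': ",
                         conditionMessage(e))
                  })
  ns <- xml2::xml_ns(doc)
  al_p <- names(ns)[startsWith(unname(ns), ALIGN_NS)]
  if (!length(al_p)) {
    stop("file does not declare the Alignment API namespace: ", path)
  }
  al_p <- al_p[[1]]
  rdf_p <- ns_prefixes_for(ns, RDF_NS)
  if (!length(rdf_p)) stop("file does not declare the RDF namespace: ", path)
  rdf_p <- rdf_p[[1]]

  onto_text <- function(tag) {
    node <- xml2::xml_find_first(doc, sprintf(".//%s:%s", al_p, tag), ns)
    if (inherits(node, "xml_missing")) return("")
    about <- xml2::xml_find_first(
      node, sprintf(".//*[@%s:about]", rdf_p), ns)
    if (!inherits(about, "xml_missing")) {
      return(xml2::xml_attr(about, "about"))
    }
    trimws(xml2::xml_text(node))
  }
  src <- source_ontology_id %||% onto_text("onto1")
  tgt <- target_ontology_id %||% onto_text("onto2")

  cells <- xml2::xml_find_all(doc, sprintf(".//%s:Cell", al_p), ns)
  src_iri <- tgt_iri <- rel <- character(length(cells))
  conf <- numeric(length(cells))
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    e1 <- xml2::xml_find_first(cell, sprintf("./%s:entity1", al_p), ns)
    e2 <- xml2::xml_find_first(cell, sprintf("./%s:entity2", al_p), ns)
    r1 <- if (inherits(e1, "xml_missing")) NA_character_ else
      xml2::xml_attr(e1, "resource")
    r2 <- if (inherits(e2, "xml_missing")) NA_character_ else
      xml2::xml_attr(e2, "resource")
    if (is.na(r1) || is.na(r2)) {
      stop("malformed Cell #", i, " in '", path,
           "': missing entity1/entity2 resource")
    }
    rnode <- xml2::xml_find_first(cell, sprintf("./%s:relation", al_p), ns)
    rsym <- if (inherits(rnode, "xml_missing")) "=" else
      trimws(xml2::xml_text(rnode))
    if (!rsym %in% names(SYMBOL_TO_RELATION)) {
      stop("malformed Cell #", i, " in '", path,
           "': unknown relation symbol '", rsym, "'")
    }
    mnode <- xml2::xml_find_first(cell, sprintf("./%s:measure", al_p), ns)
    m <- if (inherits(mnode, "xml_missing")) 1 else
      as.numeric(xml2::xml_text(mnode))
    if (is.na(m)) {
      stop("malformed Cell #", i, " in '", path, "': non-numeric measure")
    }
    src_iri[[i]] <- r1; tgt_iri[[i]] <- r2
    rel[[i]] <- SYMBOL_TO_RELATION[[rsym]]; conf[[i]] <- m
  }
  alignment(if (nzchar(src)) src else "onto1",
            if (nzchar(tgt)) tgt else "onto2",
            mappings(src_iri, tgt_iri, rel, conf),
            provenance = provenance %||% basename(path))
}

#' Write an alignment in the Alignment API RDF format
#'
#' Inverse of [read_alignment_rdf()]. One `Cell` is emitted per mapping, in
#' deterministic order (sorted by source then target iri), so the same
#' alignment always produces byte-identical output. Confidences are written
#' with full precision and round-trip exactly.
#'
#' @param al an [alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_rdf <- function(al, path) {
  stopifnot(inherits(al, "alignment"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  df <- sort_mappings(al$mappings)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<rdf:RDF xmlns=\"%s#\" xmlns:rdf=\"%s\" ",
                   "xmlns:xsd=\"http://www.w3.org/2001/XMLSchema#\">"),
            ALIGN_NS, RDF_NS),
    "  <Alignment>",
    "    <xml>yes</xml>",
    "    <level>0</level>",
    "    <type>**</type>",
    sprintf("    <onto1>%s</onto1>", esc(al$source_ontology_id)),
    sprintf("    <onto2>%s</onto2>", esc(al$target_ontology_id)))
  for (i in seq_len(nrow(df))) {
    lines <- c(lines,
      "    <map>",
      "      <Cell>",
      sprintf("        <entity1 rdf:resource=\"%s\"/>", esc(df$source_iri[[i]])),
      sprintf("        <entity2 rdf:resource=\"%s\"/>", esc(df$target_iri[[i]])),
      sprintf("        <measure rdf:datatype=\"http://www.w3.org/2001/XMLSchema#float\">%s</measure>",
              format(df$confidence[[i]], digits = 17)),
      sprintf("        <relation>%s</relation>",
              esc(RELATION_TO_SYMBOL[[df$relation[[i]]]])),
      "      </Cell>",
      "    </map>")
  }
  lines <- c(lines, "  </Alignment>", "</rdf:RDF>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an alignment from TSV
#'
#' The TSV dialect has columns `source_iri`, `target_iri`, `relation`,
#' `confidence` and optional leading comment lines
#' `#source_ontology_id=...`, `#target_ontology_id=...`, `#provenance=...`
#' written by [write_alignment_tsv()].
#'
#' @inheritParams read_alignment_rdf
#' @return an [alignment()].
#' @export
read_alignment_tsv <- function(path, source_ontology_id = NULL,
                               target_ontology_id = NULL,
                               provenance = NULL) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  all_lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", all_lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- strsplit(sub("^#", "", m), "=", fixed = TRUE)[[1]]
    if (length(kv) >= 2) meta[[kv[[1]]]] <- paste(kv[-1], collapse = "=")
  }
  body <- all_lines[!startsWith(all_lines, "#")]
  df <- utils::read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                          quote = "", colClasses = "character",
                          na.strings = character(), check.names = FALSE)
  needed <- c("source_iri", "target_iri", "relation", "confidence")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("alignment TSV is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  alignment(source_ontology_id %||% meta$source_ontology_id %||% "onto1",
            target_ontology_id %||% meta$target_ontology_id %||% "onto2",
            mappings(df$source_iri, df$target_iri, df$relation,
                     as.numeric(df$confidence)),
            provenance = provenance %||% meta$provenance %||% basename(path))
}

#' Write an alignment to TSV
#'
#' @inheritParams write_alignment_rdf
#' @return `path`, invisibly.
#' @export
write_alignment_tsv <- function(al, path) {
  stopifnot(inherits(al, "alignment"))
  df <- sort_mappings(al$mappings)[, c("source_iri", "target_iri",
                                       "relation", "confidence")]
  df$confidence <- vapply(df$confidence, format, character(1), digits = 17)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste0("#source_ontology_id=", al$source_ontology_id),
               paste0("#target_ontology_id=", al$target_ontology_id),
               paste0("#provenance=", al$provenance)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
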