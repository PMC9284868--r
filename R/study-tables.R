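#' Packaged summary tables from a published matching assessment
#'
#' The package ships, as plain TSV under `extdata`, the printed summary
#' statistics of three ontology matching systems (AgreementMakerLight 2.0,
#' FCA-Map, LogMap 2.0) run on the SNOMED CT, NCIt, and ORDO ontology
#' pairs. The underlying terminologies and the UMLS are license-restricted,
#' so only these aggregate numbers are distributed; they serve as worked
#' examples for the arithmetic helpers ([harmonic_overlap()],
#' [aggregate_means()], [format_percent()]).
#'
#' Available tables:
#' \describe{
#'   \item{alignment_sizes}{mappings per matcher and ontology pair, whole
#'     ontologies and modules.}
#'   \item{reference_overlaps}{sizes of the UMLS- and BioPortal-based
#'     reference alignments and their intersection, per pair and scope.}
#'   \item{hierarchy_counts}{counts of top-level-hierarchy-inconsistent
#'     mappings (and the candidate false positives among them), with the
#'     percentages as printed in the original report.}
#'   \item{top_level_mappings}{the manually curated pairs of semantically
#'     equivalent top-level classes per ontology pair.}
#' }
#'
#' @param name one of `"alignment_sizes"`, `"reference_overlaps"`,
#'   `"hierarchy_counts"`, `"top_level_mappings"`.
#' @return a data frame.
#' @export
#' @examples
#' ov <- study_table("reference_overlaps")
#' with(ov[ov$scope == "whole", ],
#'      format_percent(100 * harmonic_overlap(n_umls[1], n_bioportal[1],
#'                                            n_overlap[1])))
study_table <- function(name = c("alignment_sizes", "reference_overlaps",
                                 "hierarchy_counts", "top_level_mappings")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("study_", name, ".tsv"),
                      package = "ontalign", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", quote = "",
                    na.strings = character(), check.names = FALSE,
                    stringsAsFactors = FALSE)
}
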