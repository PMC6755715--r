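# Ontology ingestion: harvest class labels and synonyms from an OWL/RDF-XML
# document so that a lexicon and links table can be generated automatically.

owl_ns <- c(
  owl = "http://www.w3.org/2002/07/owl#",
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  oboInOwl = "http://www.geneontology.org/formats/oboInOwl#"
)

#' Extract a lexicon and links table from an OWL ontology
#'
#' Reads an OWL/RDF-XML document and collects, for every `owl:Class` that
#' carries its own URI (`rdf:about` or `rdf:ID`), the values of its
#' `rdfs:label`, `oboInOwl:hasExactSynonym` and `oboInOwl:hasRelatedSynonym`
#' properties. Each value becomes one lexicon term and one (term, class URI)
#' pair in the links table. Anonymous classes that nevertheless carry labels
#' are skipped with a warning. Broad/narrow synonyms are deliberately not
#' harvested.
#'
#' @param path Path to an `.owl` (RDF-XML) file, or an `xml2` document.
#' @return A list with `terms` (character vector, one per harvested value,
#'   document order) and `links` (data frame term/uri, normalized and
#'   sorted), ready for [ner_lexicon()].
#' @examples
#' \dontrun{
#' onto <- read_owl_terms("chebi.owl")
#' lex <- ner_lexicon(onto$terms, links = onto$links, name = "chebi")
#' }
#' @export
read_owl_terms <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else xml2::read_xml(path)
  classes <- xml2::xml_find_all(doc, "//owl:Class", ns = owl_ns)
  terms <- character(0)
  uris <- character(0)
  n_anon <- 0L
  for (cl in classes) {
    uri <- xml2::xml_attr(cl, "rdf:about", ns = owl_ns)
    if (is.na(uri)) {
      id <- xml2::xml_attr(cl, "rdf:ID", ns = owl_ns)
      if (!is.na(id)) uri <- paste0("#", id)
    }
    vals <- xml2::xml_text(xml2::xml_find_all(
      cl,
      "./rdfs:label | ./oboInOwl:hasExactSynonym | ./oboInOwl:hasRelatedSynonym",
      ns = owl_ns
    ))
    vals <- trimws(vals)
    vals <- vals[nzchar(vals)]
    if (length(vals) == 0L) next
    if (is.na(uri) || !nzchar(uri)) {
      n_anon <- n_anon + 1L
      next
    }
    terms <- c(terms, vals)
    uris <- c(uris, rep(uri, length(vals)))
  }
  if (n_anon > 0L) {
    warning(n_anon, " labelled owl:Class element(s) without a URI were skipped")
  }
  list(
    terms = terms,
    links = compile_links(
      data.frame(term = terms, uri = uris, stringsAsFactors = FALSE)
    )
  )
}
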