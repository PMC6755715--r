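# Shared fixtures. The worked example (four ChEBI compounds, one sentence
# mentioning them) ships with the package; everything else is built in code.

extfile <- function(f) system.file("extdata", f, package = "lexner")

example_terms <- function() {
  readLines(extfile("example_lexicon.txt"), encoding = "UTF-8")
}

example_sentence <- function() {
  readLines(extfile("example_sentence.txt"), encoding = "UTF-8")
}

example_lexicon <- function(links = FALSE) {
  ner_lexicon(
    example_terms(),
    links = if (links) extfile("example_links.tsv") else NULL,
    name = "compounds"
  )
}

# Small ChEBI-like OWL/RDF-XML document written to a temp file.
write_owl_fixture <- function(body = NULL) {
  if (is.null(body)) {
    body <- '
  <owl:Class rdf:about="http://purl.obolibrary.org/obo/CHEBI_15940">
    <rdfs:label>nicotinic acid</rdfs:label>
    <oboInOwl:hasExactSynonym>niacin</oboInOwl:hasExactSynonym>
    <oboInOwl:hasExactSynonym>pyridine-3-carboxylic acid</oboInOwl:hasExactSynonym>
    <oboInOwl:hasRelatedSynonym>vitamin B3</oboInOwl:hasRelatedSynonym>
    <oboInOwl:hasBroadSynonym>vitamin</oboInOwl:hasBroadSynonym>
  </owl:Class>
  <owl:Class rdf:about="http://purl.obolibrary.org/obo/CHEBI_18167">
    <rdfs:label>α-maltose</rdfs:label>
  </owl:Class>'
  }
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"\n',
    '         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"\n',
    '         xmlns:owl="http://www.w3.org/2002/07/owl#"\n',
    '         xmlns:oboInOwl="http://www.geneontology.org/formats/oboInOwl#">',
    body, "\n</rdf:RDF>\n"
  )
  path <- tempfile(fileext = ".owl")
  con <- file(path, open = "wb")
  writeLines(enc2utf8(doc), con, useBytes = TRUE)
  close(con)
  path
}

spans_of <- function(ann) {
  out <- ann[c("start", "end", "term")]
  rownames(out) <- NULL
  out
}
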