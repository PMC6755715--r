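Package: lexner
Title: Minimal Dictionary-Based Named-Entity Recognition and Linking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recognizes mentions of lexicon terms in free text and links
    them to ontology identifiers. A lexicon (one term per line, optionally
    with a term-to-URI links table, or extracted from an OWL/RDF-XML
    ontology) is compiled offline into a four-part word-count index.
    Annotation then runs "inverted": the words and consecutive word pairs
    of the input text are used as the patterns matched against the index,
    after which exact character offsets are resolved in the original text,
    terms are linked to URIs, and each mention receives a length-based
    confidence score. Output is plain or BeCalm-style TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
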