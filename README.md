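# lexner

Dictionary-based named-entity recognition (NER) and linking (NEL) for R.
`lexner` is aimed at researchers who have a vocabulary — a flat list of
terms, or an OWL ontology such as ChEBI, HPO or DOID — and want the
mentions of those terms in free text, with exact character offsets,
ontology URIs and a confidence score, without training a model or
assembling an annotated corpus.

## Method

The vocabulary is compiled **once, offline** into a four-part word-count
index: after normalization (lowercase; full stops removed; every other
special character replaced by the single-character wildcard `.`;
whitespace collapsed and trimmed), terms are partitioned into *one-word*,
*two-word* and *more-words* files, plus a *first-two-words* file holding
the two-word prefixes of all longer terms.

Annotation is **inverted**: instead of searching each lexicon term in the
text, the words of the processed input text — minus stop-words and words
shorter than the minimum entity length (default 3 characters) — become the
patterns. Three jobs match (1) the words against the one-word file,
(2) the consecutive word pairs against the two-word file, and (3) the
pairs against the first-two-words file, whose hits select candidate
longer terms. Because a text has far fewer words than a lexicon has
terms, this is much faster than the direct scan. Matched terms are then
located in the *original* text (case-insensitive; `.` matches any
non-space character; a word gap matches runs of whitespace/full stops;
boundaries may not touch letters or digits), which also discards
candidates that the processed text suggested but the original never
contained. Offsets are 0-based, end-exclusive, counted in Unicode
characters. Each mention of `nc` characters is linked to the first exact
match in the sorted links table and scored

```
score = 1 - 1/ln(nc)
```

so longer (less ambiguous) mentions score higher; with the default
minimum length 3 the score lies in [0.08976, 1).

## Worked example

```r
library(lexner)
ex  <- function(f) system.file("extdata", f, package = "lexner")
lex <- ner_lexicon(readLines(ex("example_lexicon.txt"), encoding = "UTF-8"),
                   links = ex("example_links.tsv"), name = "compounds")
lex
#> Compiled lexicon 'compounds'
#>   4 terms: 1 one-word, 1 two-word, 2 more-words (2 prefixes)
#>   links: 4 term-URI pairs
predict(lex, "α-maltose and nicotinic acid D-ribonucleotide was found, but not nicotinic acid")
#>   start end                         surface                            term
#> 1     0   9                       α-maltose                       α.maltose
#> 2    14  28                  nicotinic acid                  nicotinic acid
#> 3    14  45 nicotinic acid D-ribonucleotide nicotinic acid d.ribonucleotide
#> 4    65  79                  nicotinic acid                  nicotinic acid
#>                                          uri entity_type     score
#> 1 http://purl.obolibrary.org/obo/CHEBI_18167   compounds 0.5448804
#> 2 http://purl.obolibrary.org/obo/CHEBI_15940   compounds 0.6210768
#> 3 http://purl.obolibrary.org/obo/CHEBI_15763   compounds 0.7087933
#> 4 http://purl.obolibrary.org/obo/CHEBI_15940   compounds 0.6210768
```

"nicotinic acid" is found twice (offsets 14 and 65); the first occurrence
partially overlaps the longer mention "nicotinic acid D-ribonucleotide"
(14–45), which is kept — partial overlaps are allowed, only exact
duplicates are collapsed. The hyphen in "D-ribonucleotide" was indexed as
the wildcard `d.ribonucleotide`, and `α` counts as one character.

The same flow from a shell, via the bundled script (`exec/lexner`):

```sh
exec/lexner compile lexicon.txt --links links.tsv --name compounds --data-dir data
exec/lexner annotate 'α-maltose and nicotinic acid ...' --lexicon compounds --data-dir data
# 0	9	α-maltose	http://purl.obolibrary.org/obo/CHEBI_18167
# 14	28	nicotinic acid	http://purl.obolibrary.org/obo/CHEBI_15940
# ...
```

`--format becalm-tsv --doc-id 1 --section A` switches to the eight-column
annotation-server dialect (document id, section, start, end, score,
text, type, URI); `--all-lexicons` annotates with every compiled lexicon
at once, reporting terms shared by two or more lexicons under the entity
type `Unknown`.

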