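---
title: "Dictionary-based recognition and linking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dictionary-based recognition and linking: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexner)
```

## The procedure

`lexner` implements exact dictionary lookup, split into an offline and an
online half.

**Offline** (`ner_lexicon()`): every raw term is normalized — lowercase;
full stops removed; each remaining special character (not a Unicode
letter/digit, not whitespace) replaced by the wildcard `.`; whitespace
runs collapsed to single spaces; ends trimmed — deduplicated, and
partitioned by word count into the *one-word*, *two-word* and
*more-words* parts of the index; the *first-two-words* part holds the
two-word prefixes of the more-words entries. The wildcard exists because
punctuation inside terms (hyphens, slashes, primes) is written
inconsistently in running text; replacing it by "match any single
non-space character" makes `acid-adenine`, `acid/adenine` and
`acid adenine`-with-a-typo all reachable from one index entry.

**Online** (`annotate_text()` / `predict()`): the input text is
normalized with the same rules, then stop-words and words shorter than
the minimum entity length are dropped. The surviving word sequence yields
two alternation patterns — all words, and all consecutive word pairs —
and three matching jobs run against the index: words against one-word
entries, pairs against two-word entries, and pairs against
first-two-words prefixes whose hits select more-words *candidates*.
Matching is whole-entry and the wildcard is asymmetric at this stage: a
`.` in a text word stands for any non-space entry character, while a `.`
in an index entry must be met by a `.` in the text. This is exactly the
asymmetry induced by using text words as search patterns over the term
files, and it is what keeps the index stage strict (no substring hits).

Matched terms are then located in the **original** text: matching is
case-insensitive, an entry-side `.` now acts as a single non-space
wildcard, and each single space in a term matches a run of whitespace
and/or full stops (so `e coli`, the normalized form of "E. coli", still
finds "E. coli" — normalization deleted the period, location must allow
it back). Both boundaries of an occurrence must not touch a letter or
digit. This step doubles as the corrective filter for two artifacts of
the processed text: more-words candidates whose tail words never occur,
and word pairs that became adjacent only because a stop-word between
them was removed, are silently discarded because the original text does
not contain them.

Offsets are 0-based, end-exclusive and counted in Unicode characters, so
multi-byte text (Greek letters, accented characters) yields the same
annotations as ASCII. Partial overlaps are kept — a short term may sit
inside a longer one — and only exact duplicates (same term, same span)
are collapsed. Output order is (start, end, term), byte-lexicographic on
the term, purely as a determinism tie-break.

Each mention is linked to the first exact match of its normalized term
in the links table, which is sorted the way a whole-line file sort would
order it (term, then URI); a term mapped to several URIs therefore
resolves reproducibly to the smallest URI. The confidence score is
$1 - 1/\ln(nc)$ with $nc$ the character length of the annotated span —
a monotone proxy for "longer mentions are less ambiguous". The span
length (not the normalized term length) is used because the score
describes the concrete mention on the page; the two differ only when
decorations widen word gaps.

## Parameters

* `min_entity_length` (characters, default **3**): applied both to
  pattern words and to emitted spans. Two-character tokens are mostly
  spurious acronym hits in biomedical text; raising the value trades
  recall for precision.
* `stopwords` (default: packaged English function-word list,
  `ner_stopwords()`): removed from the input text before pattern
  construction, never from lexicon terms. A term *consisting only* of
  stop-words is therefore unreachable by design; a longer term may
  contain stop-words beyond its first two words and is still found.
  The list is a configuration artifact, overridable by file.

## Normalization and the wildcard: a deliberate fixed point

The five rewrite rules delete literal full stops *before* replacing
specials with `.`, so sentence punctuation never becomes a wildcard. A
naive reading of that order is not idempotent: re-normalizing
`acid.adenine` would delete the wildcard that the first pass introduced.
`ner_normalize()` therefore treats strings already in normalized form
(only lowercase letters/digits, single spaces, `.`) as fixed points and
returns them unchanged. This buys three properties the package relies
on: normalization is idempotent on all inputs, compiled index entries
are fixed points (files can be reloaded and re-fed through any path),
and the overlap lexicon — built from already-normalized terms of several
compiled lexicons — survives its own compilation. The corner case is a
*raw* input line that happens to look fully normalized (say `e.coli`):
its dot is kept as a wildcard rather than deleted. We consider that the
preferable behavior anyway — in a lexicon line the dot is almost surely
meaningful — but it is a choice, recorded here.

Unicode categories decide what is "special": `α` is a letter, survives
normalization, and counts as one character in offsets. Case folding and
matching are locale-independent (PCRE with Unicode properties; inputs
are re-marked as UTF-8 at every boundary).

## Ontology ingestion

`read_owl_terms()` harvests `rdfs:label`, `oboInOwl:hasExactSynonym` and
`oboInOwl:hasRelatedSynonym` from every `owl:Class` that carries its own
URI (`rdf:about` or `rdf:ID`). Anonymous classes are skipped with a
warning; broad/narrow synonyms are not harvested — related and exact
synonyms are how OBO ontologies record alternative *names*, whereas
broad/narrow synonyms denote different concepts and would manufacture
wrong links. Links keys are normalized with the same rules as lexicon
terms so that recognition output joins back deterministically.

## The synthetic generator and what passing tests mean

`synthetic_corpus()` emulates the structural features the matcher is
sensitive to: terms of one to five words (words ≥ 3 characters, never
stop-words in the first two positions, occasionally a stop-word further
in), word-internal special characters that compile to wildcards, carrier
text of filler and function words, and — at `decoration = "light"` —
case changes, widened word gaps and swapped special characters, i.e.
exactly the transformations the method is specified to survive.
Ground-truth offsets are recorded at planting time.

It does **not** emulate real biomedical prose: no morphological variants
(the method is exact-match by design — variants belong in the lexicon),
no nested or abbreviated mentions, no realistic token distributions.
Passing the property suites therefore demonstrates that the inverted
index is *equivalent to brute-force scanning* (`naive_annotate()`, an
independent backtracking matcher that shares only the relation
definitions, run over 500 seeded corpora) and that planted mentions are
recovered completely — it does not certify corpus-level precision or
recall on real text, which depend on the lexicon. For that,
`scripts/evaluate_corpus.R` scores the annotator against any locally
supplied gold standard.

Problem sizes in the shipped tests — up to ~15 terms and a few hundred
characters per corpus, 500 corpora in the equivalence suite, plus the
four-term worked example — were chosen to cover all index parts and
boundary cases while keeping the whole suite around ten seconds.

## Numerical and degenerate-input choices

* Scores are computed in full precision and printed with 5 decimals
  (`sprintf("%.5f")`, round-half-even), matching the minimum score
  0.08976 at length 3. `mention_score()` refuses `nc < 2`, where the
  logarithm is non-positive.
* Terms that normalize to nothing (or to bare wildcards/spaces) are
  dropped with a warning at compile time; a lexicon left empty is an
  error, an empty *annotation result* is not (exit code 0 at the CLI).
* Occurrence search is greedy (longest word gap first) and finds all
  overlapping starts via a zero-width lookahead; for a fixed start the
  greedy end is taken, which matches the brute-force oracle's
  longest-first backtracking by construction.
* Byte-lexicographic (`method = "radix"`) ordering is used for all
  sorted artifacts so results do not depend on the session locale.

## Known limitations

Only direct (wildcard-mediated) matches are found: no stemming,
lemmatization or fuzzy matching — lexical variants must be added to the
lexicon. A term whose first two words are both stop-words or short words
is unreachable. Linking is first-exact-match; no semantic
disambiguation between competing URIs is attempted. Sentence splitting,
BioC output and annotation-server plumbing are out of scope.
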