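test_that("alternation patterns are the words and consecutive pairs", {
  p <- lexner:::build_patterns(c("nicotinic", "acid", "found"))
  expect_setequal(p$one_word, c("nicotinic", "acid", "found"))
  expect_setequal(p$two_word, c("nicotinic acid", "acid found"))
  p0 <- lexner:::build_patterns(character(0))
  expect_identical(p0$one_word, character(0))
  expect_identical(p0$two_word, character(0))
  p1 <- lexner:::build_patterns("atp")
  expect_identical(p1$one_word, "atp")
  expect_identical(p1$two_word, character(0))
})

test_that("the index-time wildcard lives on the text side only", {
  expect_true(wildcard_match("acid.adenine", "acid.adenine"))
  expect_true(wildcard_match("acid", "acid"))
  expect_false(wildcard_match("acid3adenine", "acid.adenine"))
  expect_identical(wildcard_match("a.p", c("atp", "app", "amp", "at")),
                   c(TRUE, TRUE, TRUE, FALSE))
  # spaces must align with spaces: the wildcard never crosses a word gap
  expect_false(wildcard_match("ab.cd", "ab cd"))
  expect_true(wildcard_match("ab cd", "ab cd"))
  # whole-entry: no substring hits
  expect_false(wildcard_match("acid", "acids"))
  expect_identical(wildcard_match("x", character(0)), logical(0))
})

test_that("the three matching jobs hit the right index parts", {
  lex <- example_lexicon()
  expect_identical(lexner:::match_one_word(c("atp", "was"),
                                           ner_lexicon("ATP")), "atp")
  expect_identical(lexner:::match_one_word(character(0), lex), character(0))
  expect_setequal(
    lexner:::match_one_word("a.p", ner_lexicon(c("atp", "app", "xyz"))),
    c("atp", "app")
  )
  expect_identical(lexner:::match_two_word("nicotinic acid", lex),
                   "nicotinic acid")
  expect_identical(lexner:::match_two_word("acid found", lex), character(0))
  # more-words: pair matches the prefix file, then prefix selects candidates;
  # ("nicotinic","acid") does not wildcard-match "nicotinic acid.adenine"
  expect_identical(lexner:::match_more_words("nicotinic acid", lex),
                   "nicotinic acid d.ribonucleotide")
  expect_identical(lexner:::match_more_words(character(0), lex), character(0))
  expect_setequal(
    lexner:::match_more_words("nicotinic acid.adenine", lex),
    "nicotinic acid.adenine dinucleotide phosphate"
  )
})

test_that("offset resolution finds every occurrence in original characters", {
  sent <- example_sentence()
  res <- resolve_offsets("nicotinic acid", sent)
  expect_identical(res$start, c(14L, 65L))
  expect_identical(res$end, c(28L, 79L))
  expect_identical(res$surface, c("nicotinic acid", "nicotinic acid"))
  # surface consistency in Unicode characters
  expect_identical(substr(sent, res$start[1] + 1, res$end[1]),
                   res$surface[1])
  expect_identical(nrow(resolve_offsets("absent term", sent)), 0L)
  # entry-side wildcard matches any single non-space character
  r2 <- resolve_offsets("α.maltose", sent)
  expect_identical(r2$start, 0L)
  expect_identical(r2$surface, "α-maltose")
  # a term space matches runs of whitespace and removed full stops
  r3 <- resolve_offsets("e coli", "Found E. coli and E  coli.")
  expect_identical(r3$start, c(6L, 18L))
  expect_identical(r3$surface, c("E. coli", "E  coli"))
  # boundaries must not touch letters or digits
  expect_identical(nrow(resolve_offsets("atp", "xxatp and atp3")), 0L)
  expect_identical(resolve_offsets("atp", "(atp) atp.")$start, c(1L, 6L))
  # spans below the minimum entity length are suppressed
  expect_identical(nrow(resolve_offsets("ab", "ab here",
                                        ner_config(min_entity_length = 3))),
                   0L)
})

test_that("the full pipeline reproduces the worked example", {
  lex <- example_lexicon()
  ann <- annotate_text(example_sentence(), lex)
  expect_identical(ann$start, c(0L, 14L, 14L, 65L))
  expect_identical(ann$end, c(9L, 28L, 45L, 79L))
  expect_identical(
    ann$surface,
    c("α-maltose", "nicotinic acid",
      "nicotinic acid D-ribonucleotide", "nicotinic acid")
  )
  # the shorter term overlaps the longer one without suppressing it
  expect_identical(ann$term[2], "nicotinic acid")
  expect_identical(ann$term[3], "nicotinic acid d.ribonucleotide")
  expect_identical(ann$entity_type, rep("compounds", 4))
  expect_true(all(is.na(ann$uri)))
  # predict() is the same operation
  expect_identical(predict(lex, example_sentence()), ann)
})

test_that("annotations satisfy their invariants on random corpora", {
  cfg <- ner_config()
  for (seed in 1:25) {
    cp <- synthetic_corpus(seed, n_terms = 8, n_mentions = 5,
                           decoration = if (seed %% 2) "none" else "light")
    lex <- ner_lexicon(cp$terms)
    ann <- annotate_text(cp$text, lex, cfg)
    n <- nchar(cp$text, type = "chars")
    if (nrow(ann) == 0) next
    expect_true(all(ann$start >= 0 & ann$start < ann$end & ann$end <= n))
    expect_true(all(ann$end - ann$start >= cfg$min_entity_length))
    expect_identical(ann$surface,
                     substring(cp$text, ann$start + 1, ann$end))
    # surfaces normalize into something the term accepts at locate time
    expect_true(all(mapply(function(s, t) {
      nrow(resolve_offsets(t, s, ner_config(min_entity_length = 1))) > 0
    }, ann$surface, ann$term)))
    # no surface is only stop-words
    surf_words <- lapply(strsplit(ner_normalize(ann$surface), " "), setdiff,
                         y = cfg$stopwords)
    expect_true(all(lengths(surf_words) > 0))
    # no exact duplicates
    expect_false(any(duplicated(ann[c("start", "end", "term")])))
    # deterministic
    expect_identical(annotate_text(cp$text, lex, cfg), ann)
  }
})

test_that("growing the lexicon never removes annotations", {
  for (seed in 1:10) {
    cp <- synthetic_corpus(seed + 500, n_terms = 6, n_mentions = 4)
    base <- annotate_text(cp$text, ner_lexicon(cp$terms))
    grown <- annotate_text(cp$text,
                           ner_lexicon(c(cp$terms, "zzz new term")))
    key <- function(a) paste(a$start, a$end, a$term)
    expect_true(all(key(base) %in% key(grown)))
  }
})

test_that("degenerate inputs give empty annotation sets or clear errors", {
  lex <- example_lexicon()
  expect_identical(nrow(annotate_text("", lex)), 0L)
  expect_identical(nrow(annotate_text("was", lex)), 0L)
  expect_error(annotate_text("text", list(one_word = "x")), "ner_lexicon")
  # pair spanning a removed stop-word is discarded at offset resolution
  lex2 <- ner_lexicon("nicotinic acid")
  expect_identical(nrow(annotate_text("nicotinic was acid", lex2)), 0L)
  # stop-words can never be annotated even if present in the lexicon
  lex3 <- ner_lexicon(c("was", "acid"))
  ann <- annotate_text("it was acid", lex3)
  expect_identical(ann$term, "acid")
})
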