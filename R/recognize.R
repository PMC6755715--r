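# Online module: inverted recognition. The words (and consecutive word
# pairs) of the processed input text are the patterns, matched against the
# compiled index; matched terms are then located exactly in the original
# text. Matching against the index is whole-entry: a pattern word matches a
# one-word entry only in full, so substrings never hit longer entries except
# through the dedicated first-two-words prefix path.

# One-word and two-word alternation patterns from the content-word sequence.
# Pairs are adjacent in the *filtered* sequence: removing a stop-word can
# make two originally non-adjacent words a pair; offset resolution against
# the original text is the corrective filter that discards such pairs.
build_patterns <- function(content_words) {
  n <- length(content_words)
  list(
    one_word = unique(content_words),
    two_word = if (n >= 2L) {
      unique(paste(content_words[-n], content_words[-1L]))
    } else {
      character(0)
    }
  )
}

#' Wildcard match between a text pattern and an index entry
#'
#' The index-time match relation of inverted recognition: `candidate` (a
#' normalized word or phrase from the input text) matches an entry iff both
#' have the same length and, position by position, the characters are equal
#' or the candidate character is the wildcard `'.'` (which matches any entry
#' character except a space — spaces must align with spaces). The wildcard is
#' asymmetric here: an entry-side `'.'` requires a `'.'` in the candidate;
#' entry-side wildcards only become single-character wildcards later, at
#' offset-resolution time (see [resolve_offsets()]).
#'
#' @param candidate A single normalized string.
#' @param entries Character vector of normalized index entries.
#' @return Logical vector along `entries`.
#' @examples
#' wildcard_match("acid.adenine", "acid.adenine")
#' wildcard_match("a.p", c("atp", "app", "amp", "at"))
#' @export
wildcard_match <- function(candidate, entries) {
  if (length(entries) == 0L) return(logical(0))
  cand <- strsplit(candidate, "")[[1L]]
  n <- length(cand)
  wild <- cand == "."
  vapply(strsplit(entries, ""), function(ec) {
    length(ec) == n && all(ec == cand | (wild & ec != " "))
  }, logical(1), USE.NAMES = FALSE)
}

match_entries <- function(patterns, entries) {
  if (length(patterns) == 0L || length(entries) == 0L) return(character(0))
  exact <- patterns[!grepl(".", patterns, fixed = TRUE)]
  fuzzy <- patterns[grepl(".", patterns, fixed = TRUE)]
  hits <- entries[entries %in% exact]
  for (p in fuzzy) hits <- c(hits, entries[wildcard_match(p, entries)])
  unique(hits)
}

# Job 1: text words against the one-word file.
match_one_word <- function(one_word_pattern, lex) {
  match_entries(one_word_pattern, lex$one_word)
}

# Job 2: consecutive word pairs against the two-word file.
match_two_word <- function(two_word_pattern, lex) {
  match_entries(two_word_pattern, lex$two_word)
}

# Job 3: pairs against the first-two-words file, then every more-words term
# whose two-word prefix equals a stage-1 hit. Results are candidates only:
# they are emitted solely when confirmed by resolve_offsets().
match_more_words <- function(two_word_pattern, lex) {
  stage1 <- match_entries(two_word_pattern, lex$first_two_words)
  if (length(stage1) == 0L) return(character(0))
  lex$more_words[first_two_words(lex$more_words) %in% stage1]
}

# Locate-time regex for one normalized term: a literal character matches
# itself case-insensitively; '.' matches any single non-whitespace
# character; each single space matches one or more whitespace or full-stop
# characters (so terms survive the removal of sentence periods). Match
# boundaries must not touch a letter or digit. The whole body sits inside a
# lookahead capture so that overlapping occurrences are all found.
term_locate_regex <- function(term) {
  chars <- strsplit(term, "")[[1L]]
  body <- paste(vapply(chars, function(ch) {
    if (ch == ".") "\\S" else if (ch == " ") "[\\s.]+" else ch
  }, character(1)), collapse = "")
  paste0("(*UCP)(?i)(?<![\\p{L}\\p{N}])(?=(", body, ")(?![\\p{L}\\p{N}]))")
}

#' Locate terms in the original text
#'
#' For each normalized term, finds every occurrence in the unmodified input
#' text (case-insensitive; `'.'` in the term matches any single non-space
#' character; a space in the term matches a run of whitespace and/or full
#' stops; occurrence boundaries must not be adjacent to a letter or digit).
#' Offsets are 0-based, end-exclusive, counted in Unicode characters, so the
#' same annotation is produced for single-byte and multi-byte text.
#' Occurrences shorter than `config$min_entity_length` characters are
#' dropped; terms with zero occurrences yield no rows.
#'
#' @param terms Character vector of normalized terms (index entries).
#' @param text The original input text (single string).
#' @param config A [ner_config()] object.
#' @return Data frame with columns `start`, `end`, `surface`, `term`.
#' @examples
#' resolve_offsets("e coli", "Found E. coli here", ner_config())
#' @export
resolve_offsets <- function(terms, text, config = ner_config()) {
  stopifnot(length(text) == 1L)
  text <- enc2utf8(text)
  out <- list()
  for (term in unique(terms)) {
    m <- gregexpr(term_locate_regex(term), text, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    cs <- as.vector(attr(m, "capture.start")[, 1L])
    cl <- as.vector(attr(m, "capture.length")[, 1L])
    keep <- cl >= config$min_entity_length
    if (!any(keep)) next
    cs <- cs[keep]
    cl <- cl[keep]
    out[[length(out) + 1L]] <- data.frame(
      start = cs - 1L,
      end = cs - 1L + cl,
      surface = substring(text, cs, cs + cl - 1L),
      term = term,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      surface = character(0), term = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- unique(res)
  res <- res[order(res$start, res$end, res$term, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate free text with a compiled lexicon
#'
#' The full online pipeline: normalize the text, drop stop-words and short
#' words, build the one-word and two-word alternation patterns, run the
#' three matching jobs against the index, locate every matched term in the
#' original text, attach URIs from the links table (first exact match wins)
#' and compute the confidence score `1 - 1/ln(nc)` where `nc` is the length
#' of the annotated span in characters. Partial overlaps are kept (a shorter
#' term may share a position with a longer one); exact duplicates (same
#' term, same span) are collapsed. Rows are sorted by start, end, term.
#'
#' @param text A single string (UTF-8) to annotate.
#' @param lexicon A compiled [ner_lexicon()].
#' @param config A [ner_config()] object.
#' @return Data frame with one row per mention and columns `start`, `end`
#'   (0-based character offsets, end-exclusive), `surface` (original-text
#'   substring), `term` (matched normalized term), `uri` (`NA` when the term
#'   has no link or no links table is attached), `entity_type` (the lexicon
#'   name) and `score`.
#' @examples
#' lex <- ner_lexicon(c("nicotinic acid", "ATP"))
#' annotate_text("ATP and nicotinic acid were detected.", lex)
#' @export
annotate_text <- function(text, lexicon, config = ner_config()) {
  if (!inherits(lexicon, "ner_lexicon")) {
    stop("'lexicon' must be a compiled ner_lexicon object")
  }
  stopifnot(inherits(config, "ner_config"), length(text) == 1L, !is.na(text))
  text <- enc2utf8(text)
  content <- ner_content_words(ner_tokenize(ner_normalize(text)), config)
  pat <- build_patterns(content)
  matched <- unique(c(
    match_one_word(pat$one_word, lexicon),
    match_two_word(pat$two_word, lexicon),
    match_more_words(pat$two_word, lexicon)
  ))
  res <- resolve_offsets(matched, text, config)
  res$uri <- if (is.null(lexicon$links)) {
    rep(NA_character_, nrow(res))
  } else {
    vapply(res$term, link_term, character(1), links = lexicon$links,
           USE.NAMES = FALSE)
  }
  res$entity_type <- rep(lexicon$name, nrow(res))
  res$score <- if (nrow(res)) mention_score(res$end - res$start) else numeric(0)
  attr(res, "linked") <- !is.null(lexicon$links)
  res
}

#' Annotate text with a compiled lexicon (predict method)
#'
#' `predict` on a compiled lexicon annotates new text; equivalent to
#' [annotate_text()].
#'
#' @param object A [ner_lexicon()] object.
#' @param text Text to annotate (single string).
#' @param config A [ner_config()] object.
#' @param ... Unused.
#' @return See [annotate_text()].
#' @export
predict.ner_lexicon <- function(object, text, config = ner_config(), ...) {
  annotate_text(text, object, config)
}
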