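# Test support: seeded synthetic (lexicon, text) corpora with planted
# ground-truth mentions, and an independent brute-force recognizer used as
# an oracle in equivalence tests. The oracle shares only the *definitions*
# of the normalize and locate relations; it scans the text with a
# hand-written backtracking matcher, no index, no pattern inversion, no
# regular expressions.

filler_pool <- c(
  "patient", "sample", "levels", "study", "measured", "observed", "protein",
  "serum", "results", "control", "showed", "increase", "analysis", "blood",
  "tissue", "after", "treatment", "values", "normal", "reported", "clinical",
  "subjects", "weeks", "baseline", "compared", "group", "higher", "lower"
)
stop_fillers <- c("and", "the", "was", "but", "not", "with", "for", "of")
specials_pool <- c("-", "/", "+", "'")

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# term words must stay discoverable: not a filler, not any stop-word of the
# default configuration
rand_word <- function(min_len = 3L, max_len = 8L) {
  repeat {
    w <- paste(sample(letters, sample(min_len:max_len, 1L), replace = TRUE),
               collapse = "")
    if (!(w %in% filler_pool) && !(w %in% stop_fillers) &&
        !(w %in% ner_stopwords())) {
      return(w)
    }
  }
}

# sample() treats a length-1 numeric vector as 1:x; this always samples
# from the given set
pick <- function(x) x[sample.int(length(x), 1L)]

rand_term <- function() {
  n <- sample(1:5, 1L, prob = c(0.3, 0.3, 0.2, 0.12, 0.08))
  words <- vapply(seq_len(n), function(i) rand_word(), character(1))
  # middle words of long terms may be stop-words: only the first two words
  # need to be discoverable as patterns
  if (n >= 3L && stats::runif(1) < 0.25) {
    words[pick(3:n)] <- pick(stop_fillers)
  }
  # occasionally join two halves of a word with a special character so the
  # normalized term carries a wildcard
  if (stats::runif(1) < 0.35) {
    i <- pick(seq_len(n))
    w <- words[i]
    if (nchar(w) >= 6L) {
      cut <- pick(3:(nchar(w) - 3L))
      words[i] <- paste0(substr(w, 1L, cut), pick(specials_pool),
                         substr(w, cut + 1L, nchar(w)))
    }
  }
  paste(words, collapse = " ")
}

decorate <- function(surface, level) {
  if (level == "none") return(surface)
  chars <- strsplit(surface, "")[[1L]]
  # flip case of some letters: matching is case-insensitive
  flip <- stats::runif(length(chars)) < 0.3 & grepl("[a-z]", chars)
  chars[flip] <- toupper(chars[flip])
  # swap special characters for other specials: both normalize to '.'
  # and '.' locates any non-space character
  sp <- chars %in% specials_pool
  chars[sp] <- sample(specials_pool, sum(sp), replace = TRUE)
  out <- paste(chars, collapse = "")
  # widen word gaps: a term space locates one or more whitespace characters
  if (stats::runif(1) < 0.5) out <- sub(" ", "  ", out)
  out
}

#' Generate a synthetic annotated corpus
#'
#' Builds a random lexicon of 1-5-word terms (word length >= 3; some words
#' joined by special characters so normalized terms carry wildcards), then
#' plants `n_mentions` term occurrences into carrier text made of filler and
#' stop-words, recording exact character offsets as ground truth. Only
#' transformations the matcher is designed to survive are applied when
#' `decoration = "light"`: case changes, widened word gaps, and substitution
#' of one special character for another. Alphanumeric characters of planted
#' terms are never altered (matching is exact by design). The same seed
#' always yields the identical corpus.
#'
#' @param seed Integer seed.
#' @param n_terms Number of lexicon terms (>= 1).
#' @param n_mentions Number of planted mentions (0 allowed).
#' @param decoration `"none"` (plant terms verbatim) or `"light"`.
#' @return An object of class `ner_corpus`: a list with `seed`, `terms`
#'   (raw lexicon), `text`, and `truth` (data frame `start`, `end`, `term`
#'   with 0-based end-exclusive character offsets and normalized terms).
#' @examples
#' cp <- synthetic_corpus(1, n_terms = 5, n_mentions = 3)
#' cp$truth
#' @export
synthetic_corpus <- function(seed, n_terms = 8L, n_mentions = 6L,
                             decoration = c("none", "light")) {
  decoration <- match.arg(decoration)
  stopifnot(n_terms >= 1L, n_mentions >= 0L)
  with_seed(seed, {
    terms <- unique(vapply(seq_len(n_terms), function(i) rand_term(),
                           character(1)))
    planted <- if (n_mentions > 0L) {
      sample(terms, n_mentions, replace = TRUE)
    } else {
      character(0)
    }
    fillers <- function(k) sample(c(filler_pool, stop_fillers), k,
                                  replace = TRUE)
    pieces <- fillers(sample(1:3, 1L))
    truth <- list()
    for (tm in planted) {
      surface <- decorate(tm, decoration)
      prefix <- paste(pieces, collapse = " ")
      start <- nchar(prefix, type = "chars") + 1L  # +1 for joining space
      truth[[length(truth) + 1L]] <- data.frame(
        start = start,
        end = start + nchar(surface, type = "chars"),
        term = ner_normalize(tm),
        stringsAsFactors = FALSE
      )
      pieces <- c(pieces, surface, fillers(sample(1:3, 1L)))
    }
    truth <- if (length(truth)) {
      do.call(rbind, truth)
    } else {
      data.frame(start = integer(0), end = integer(0), term = character(0),
                 stringsAsFactors = FALSE)
    }
    structure(
      list(seed = seed, terms = terms,
           text = paste(pieces, collapse = " "), truth = truth),
      class = "ner_corpus"
    )
  })
}

#' @export
print.ner_corpus <- function(x, ...) {
  cat(sprintf("Synthetic corpus (seed %s): %d terms, %d planted mentions, %d chars\n",
              format(x$seed), length(x$terms), nrow(x$truth),
              nchar(x$text, type = "chars")))
  invisible(x)
}

#' Save / load a synthetic corpus
#'
#' Serializes a corpus to a directory as plain text (`text.txt`,
#' `lexicon.txt`, `truth.tsv`), e.g. to freeze a golden fixture.
#'
#' @param corpus A [synthetic_corpus()] object.
#' @param dir Directory.
#' @return `write_corpus()`: invisibly, the directory; `read_corpus()`:
#'   a list with `terms`, `text`, `truth`.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "ner_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_lines_utf8(corpus$text, file.path(dir, "text.txt"))
  write_lines_utf8(corpus$terms, file.path(dir, "lexicon.txt"))
  write_lines_utf8(
    paste(corpus$truth$start, corpus$truth$end, corpus$truth$term, sep = "\t"),
    file.path(dir, "truth.tsv")
  )
  invisible(dir)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  truth_lines <- readLines(file.path(dir, "truth.tsv"), encoding = "UTF-8")
  parts <- strsplit(truth_lines, "\t", fixed = TRUE)
  list(
    terms = readLines(file.path(dir, "lexicon.txt"), encoding = "UTF-8"),
    text = paste(readLines(file.path(dir, "text.txt"), encoding = "UTF-8"),
                 collapse = "\n"),
    truth = data.frame(
      start = as.integer(vapply(parts, `[[`, character(1), 1L)),
      end = as.integer(vapply(parts, `[[`, character(1), 2L)),
      term = vapply(parts, `[[`, character(1), 3L),
      stringsAsFactors = FALSE
    )
  )
}

# --- independent oracle ----------------------------------------------------

is_alnum_char <- function(ch) grepl("(*UCP)[\\p{L}\\p{N}]", ch, perl = TRUE)
is_space_char <- function(ch) grepl("(*UCP)\\s", ch, perl = TRUE)

# Position-by-position wildcard comparison, written independently of
# wildcard_match(): candidate wildcard '.' may stand for any non-space
# entry character.
naive_pair_match <- function(candidate, entry) {
  cc <- strsplit(candidate, "")[[1L]]
  ec <- strsplit(entry, "")[[1L]]
  if (length(cc) != length(ec)) return(FALSE)
  for (i in seq_along(cc)) {
    ok <- cc[i] == ec[i] || (cc[i] == "." && ec[i] != " ")
    if (!ok) return(FALSE)
  }
  TRUE
}

# Backtracking scan for one term occurrence starting at text position ti
# (1-based; tc_low = lowercased text chars, gapv/spacev precomputed per
# char). Returns the end position (inclusive) or -1. Word gaps are consumed
# greedily, longest first, like the recognizer's regex engine would.
naive_match_at <- function(tc_low, gapv, spacev, mc, ti, mi) {
  if (mi > length(mc)) return(ti - 1L)
  if (ti > length(tc_low)) return(-1L)
  ch <- mc[mi]
  if (ch == " ") {
    j <- ti
    while (j <= length(tc_low) && gapv[j]) j <- j + 1L
    if (j == ti) return(-1L)
    for (k in seq.int(j - 1L, ti)) {
      res <- naive_match_at(tc_low, gapv, spacev, mc, k + 1L, mi + 1L)
      if (res > 0L) return(res)
    }
    return(-1L)
  }
  ok <- if (ch == ".") !spacev[ti] else tc_low[ti] == ch
  if (!ok) return(-1L)
  naive_match_at(tc_low, gapv, spacev, mc, ti + 1L, mi + 1L)
}

#' Brute-force recognition oracle
#'
#' Reference implementation used to validate [annotate_text()]: every
#' lexicon term is independently checked against the content words of the
#' text (a term is discoverable when one of the text's words, consecutive
#' word pairs, or — for terms of three or more words — its two-word prefix
#' matches), and each discoverable term is then located by scanning the
#' original text character by character with a backtracking matcher under
#' the same locate relation as [resolve_offsets()]. No index is built and no
#' regular expressions are used, so agreement with [annotate_text()] is a
#' meaningful cross-check rather than a tautology.
#'
#' @param text A single string.
#' @param terms Raw lexicon (character vector, as for [ner_lexicon()]).
#' @param config A [ner_config()] object.
#' @return Data frame with columns `start`, `end`, `term`, sorted by
#'   (start, end, term).
#' @export
naive_annotate <- function(text, terms, config = ner_config()) {
  text <- enc2utf8(text)
  norm_terms <- unique(ner_normalize(terms))
  norm_terms <- norm_terms[nzchar(norm_terms) & !grepl("^[. ]+$", norm_terms)]
  content <- ner_content_words(ner_tokenize(ner_normalize(text)), config)
  pairs <- if (length(content) >= 2L) {
    paste(content[-length(content)], content[-1L])
  } else {
    character(0)
  }
  tc <- strsplit(text, "")[[1L]]
  tc_low <- tolower(tc)
  alnumv <- is_alnum_char(tc)
  spacev <- is_space_char(tc)
  gapv <- spacev | tc == "."
  out <- list()
  for (term in norm_terms) {
    nw <- length(strsplit(term, " ", fixed = TRUE)[[1L]])
    probe <- if (nw <= 2L) term else first_two_words(term)
    against <- if (nw == 1L) content else pairs
    discoverable <- any(vapply(against, naive_pair_match, logical(1),
                               entry = probe))
    if (!discoverable) next
    mc <- strsplit(term, "")[[1L]]
    for (ti in seq_along(tc)) {
      if (ti > 1L && alnumv[ti - 1L]) next
      endi <- naive_match_at(tc_low, gapv, spacev, mc, ti, 1L)
      if (endi < 0L) next
      if (endi < length(tc) && alnumv[endi + 1L]) next
      if (endi - ti + 1L < config$min_entity_length) next
      out[[length(out) + 1L]] <- data.frame(
        start = ti - 1L, end = endi, term = term, stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) {
    unique(do.call(rbind, out))
  } else {
    data.frame(start = integer(0), end = integer(0), term = character(0),
               stringsAsFactors = FALSE)
  }
  res <- res[order(res$start, res$end, res$term, method = "radix"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
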