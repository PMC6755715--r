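# Shared text-rewriting rules, applied both to lexicon terms (offline) and to
# the input text (online). A "special" character is anything that is neither
# alphanumeric (Unicode letter/digit) nor whitespace; after normalization it
# appears as the single-character wildcard '.'.

.lexner <- new.env(parent = emptyenv())

#' Normalization and matching configuration
#'
#' Bundles the tunable parameters of the online annotation step: the
#' stop-word list and the minimum entity length. Stop-words and words shorter
#' than `min_entity_length` characters are removed from the input text before
#' patterns are built, and no annotation shorter than `min_entity_length`
#' characters is ever emitted. The defaults (length 3, packaged English
#' stop-word list) reflect that two-character acronym matches are mostly
#' spurious in biomedical text.
#'
#' @param min_entity_length Minimum mention length in characters (>= 1).
#' @param stopwords Character vector of stop-words; normalized (lowercased)
#'   internally. See [ner_stopwords()].
#' @return An object of class `ner_config`.
#' @examples
#' cfg <- ner_config()
#' cfg$min_entity_length
#' @export
ner_config <- function(min_entity_length = 3L, stopwords = ner_stopwords()) {
  min_entity_length <- as.integer(min_entity_length)
  if (length(min_entity_length) != 1L || is.na(min_entity_length) ||
      min_entity_length < 1L) {
    stop("'min_entity_length' must be a single integer >= 1")
  }
  stopwords <- unique(ner_normalize(as.character(stopwords)))
  stopwords <- stopwords[nzchar(stopwords)]
  structure(
    list(min_entity_length = min_entity_length, stopwords = stopwords),
    class = "ner_config"
  )
}

#' Default stop-word list
#'
#' Reads a stop-word file (plain text, UTF-8, one word per line). With no
#' argument, returns the list packaged with lexner. The exact list is a
#' configuration artifact: swap in your own file to change which function
#' words are ignored during annotation.
#'
#' @param path Optional path to a stop-word file.
#' @return Character vector of lowercase stop-words.
#' @export
ner_stopwords <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.lexner$stopwords)) {
      default <- system.file("extdata", "stopwords.txt", package = "lexner")
      .lexner$stopwords <- readLines(default, encoding = "UTF-8")
    }
    return(.lexner$stopwords)
  }
  if (!file.exists(path)) stop("stop-word file not found: ", path)
  readLines(path, encoding = "UTF-8")
}

# TRUE for strings already in normalized form: only lowercase (caseless)
# letters, digits, '.' wildcards and single internal spaces.
is_normalized <- function(x) {
  x == tolower(x) &
    !grepl("(*UCP)[^\\p{L}\\p{N}. ]", x, perl = TRUE) &
    !grepl("  ", x, fixed = TRUE) &
    !grepl("^ | $", x)
}

#' Normalize text for matching
#'
#' Applies, in order: lowercase; remove full stops; replace every special
#' character (not alphanumeric, not whitespace) with the wildcard '.';
#' collapse each whitespace run to a single space; strip leading/trailing
#' spaces. The result contains only lowercase alphanumerics, single spaces
#' and '.' wildcards. Strings already in that form are returned unchanged,
#' which makes the function idempotent (so compiled index entries such as
#' `"acid.adenine"` are fixed points). Alphanumeric is decided by Unicode
#' categories: Greek letters and other multi-byte characters are letters,
#' not specials.
#'
#' @param x Character vector.
#' @return Character vector of the same length, UTF-8.
#' @examples
#' ner_normalize("nicotinic acid-adenine dinucleotide phosphate")
#' ner_normalize("  E. coli  ")
#' @export
ner_normalize <- function(x) {
  x <- enc2utf8(as.character(x))
  if (length(x) == 0L) return(character(0))
  keep <- is_normalized(x)
  y <- tolower(x)
  y <- gsub(".", "", y, fixed = TRUE)
  y <- gsub("(*UCP)[^\\p{L}\\p{N}\\s]", ".", y, perl = TRUE)
  y <- gsub("(*UCP)\\s+", " ", y, perl = TRUE)
  y <- gsub("^ | $", "", y)
  x[!keep] <- y[!keep]
  x
}

#' Split a normalized string into words
#'
#' A word is a maximal run of non-space characters; joining the result with
#' single spaces reproduces the input.
#'
#' @param x A single normalized string (see [ner_normalize()]).
#' @return Character vector of words (empty for `""`).
#' @export
ner_tokenize <- function(x) {
  stopifnot(length(x) == 1L)
  if (!nzchar(x)) return(character(0))
  strsplit(x, " ", fixed = TRUE)[[1L]]
}

#' Drop stop-words and short words
#'
#' Returns the subsequence of `words` that are not stop-words and have at
#' least `config$min_entity_length` characters, preserving order. Applied to
#' the input text only (never to lexicon terms) before patterns are built.
#'
#' @param words Character vector of normalized words.
#' @param config A [ner_config()] object.
#' @return Character vector, a subsequence of `words`.
#' @export
ner_content_words <- function(words, config = ner_config()) {
  stopifnot(inherits(config, "ner_config"))
  words[!(words %in% config$stopwords) &
          nchar(words, type = "chars") >= config$min_entity_length]
}
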