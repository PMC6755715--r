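# Offline compiler: a raw term list becomes a four-part word-count index.
# Terms are normalized, deduplicated and partitioned by word count into
# one-word / two-word / more-words, plus the first-two-words prefix file that
# lets three-plus-word terms be discovered from two-word patterns.

radix_sort <- function(x) x[order(x, method = "radix")]

first_two_words <- function(terms) {
  sub("^(\\S+ \\S+) .*$", "\\1", terms, perl = TRUE)
}

#' Compile a lexicon into the four-part index
#'
#' The fitting step of the package: takes the raw vocabulary (one term per
#' element), normalizes it with [ner_normalize()], removes duplicates, and
#' partitions terms by word count into the `one_word`, `two_word` and
#' `more_words` parts; `first_two_words` holds the two-word prefixes of all
#' `more_words` entries. Terms that normalize to nothing (or to bare
#' wildcards/spaces) are dropped with a warning.
#'
#' @param terms Character vector of raw terms.
#' @param links Optional links table: a two-column data frame (term, uri) or
#'   a path to a two-column TSV file (term TAB URI, no header). Terms are
#'   normalized and the table is sorted byte-lexicographically; when a term
#'   maps to several URIs all pairs are kept and lookup returns the first.
#' @param name Identifier for the lexicon; used as file-name prefix by
#'   [write_lexicon()] and as the annotation entity type.
#' @return An object of class `ner_lexicon` with components `name`,
#'   `one_word`, `two_word`, `more_words`, `first_two_words` (unique
#'   prefixes) and `links` (data frame or `NULL`).
#' @examples
#' lex <- ner_lexicon(c("ATP", "nicotinic acid",
#'                      "nicotinic acid D-ribonucleotide"))
#' lex
#' @seealso [predict.ner_lexicon()], [annotate_text()], [write_lexicon()]
#' @export
ner_lexicon <- function(terms, links = NULL, name = "lexicon") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  terms <- enc2utf8(as.character(terms))
  terms <- terms[!is.na(terms)]
  terms <- trimws(terms)
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L) stop("empty lexicon: no terms to compile")
  norm <- ner_normalize(terms)
  bad <- !nzchar(norm) | grepl("^[. ]+$", norm)
  if (any(bad)) {
    warning(sum(bad), " term(s) normalized to nothing and were dropped")
    norm <- norm[!bad]
  }
  if (length(norm) == 0L) stop("empty lexicon: no terms left after cleanup")
  norm <- radix_sort(unique(norm))
  nwords <- lengths(strsplit(norm, " ", fixed = TRUE))
  more <- norm[nwords >= 3L]
  structure(
    list(
      name = name,
      one_word = norm[nwords == 1L],
      two_word = norm[nwords == 2L],
      more_words = more,
      first_two_words = radix_sort(unique(first_two_words(more))),
      links = compile_links(links)
    ),
    class = "ner_lexicon"
  )
}

# Normalize and sort a links table; accepts a data frame or a TSV path.
compile_links <- function(links) {
  if (is.null(links)) return(NULL)
  if (is.character(links) && length(links) == 1L) links <- read_links(links)
  stopifnot(is.data.frame(links), ncol(links) >= 2L)
  tab <- data.frame(
    term = ner_normalize(links[[1L]]),
    uri = enc2utf8(as.character(links[[2L]])),
    stringsAsFactors = FALSE
  )
  tab <- tab[nzchar(tab$term) & !grepl("^[. ]+$", tab$term), , drop = FALSE]
  tab <- unique(tab)
  # whole-line sort: duplicate terms are ordered by URI, first match wins
  tab <- tab[order(tab$term, tab$uri, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

read_links <- function(path) {
  if (!file.exists(path)) stop("links file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("links file must have 2 tab-separated columns: ", path)
  data.frame(
    term = vapply(parts, `[[`, character(1), 1L),
    uri = vapply(parts, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ner_lexicon <- function(x, ...) {
  cat("Compiled lexicon '", x$name, "'\n", sep = "")
  cat(sprintf(
    "  %d terms: %d one-word, %d two-word, %d more-words (%d prefixes)\n",
    length(x$one_word) + length(x$two_word) + length(x$more_words),
    length(x$one_word), length(x$two_word), length(x$more_words),
    length(x$first_two_words)
  ))
  if (!is.null(x$links)) {
    cat(sprintf("  links: %d term-URI pairs\n", nrow(x$links)))
  }
  invisible(x)
}

#' @export
summary.ner_lexicon <- function(object, ...) {
  print(object)
  show <- function(label, v) {
    if (length(v)) {
      cat("  ", label, ": ", paste(utils::head(v, 3L), collapse = "; "),
          if (length(v) > 3L) " ..." else "", "\n", sep = "")
    }
  }
  show("one-word", object$one_word)
  show("two-word", object$two_word)
  show("more-words", object$more_words)
  show("first-two-words", object$first_two_words)
  invisible(object)
}

compiled_parts <- c("_word1.txt", "_word2.txt", "_words.txt", "_words2.txt")

#' Write a compiled lexicon to disk
#'
#' Saves the four index files (`<name>_word1.txt`, `<name>_word2.txt`,
#' `<name>_words.txt`, `<name>_words2.txt`; one term per line, UTF-8) plus
#' `<name>_links.tsv` when a links table is attached. [read_lexicon()] is the
#' exact inverse.
#'
#' @param lex A [ner_lexicon()] object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_lexicon <- function(lex, dir = ".") {
  stopifnot(inherits(lex, "ner_lexicon"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  parts <- list(lex$one_word, lex$two_word, lex$more_words, lex$first_two_words)
  paths <- file.path(dir, paste0(lex$name, compiled_parts))
  for (i in seq_along(parts)) {
    con <- file(paths[i], open = "wb")
    writeLines(enc2utf8(parts[[i]]), con, useBytes = TRUE)
    close(con)
  }
  if (!is.null(lex$links)) {
    lp <- file.path(dir, paste0(lex$name, "_links.tsv"))
    con <- file(lp, open = "wb")
    writeLines(enc2utf8(paste(lex$links$term, lex$links$uri, sep = "\t")),
               con, useBytes = TRUE)
    close(con)
    paths <- c(paths, lp)
  }
  invisible(paths)
}

#' Load a compiled lexicon from disk
#'
#' @param name Lexicon identifier (the file-name prefix used by
#'   [write_lexicon()]).
#' @param dir Directory holding the compiled files.
#' @return A `ner_lexicon` object; error naming the missing part if the
#'   lexicon was not compiled.
#' @export
read_lexicon <- function(name, dir = ".") {
  paths <- file.path(dir, paste0(name, compiled_parts))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("lexicon '", name, "' is not compiled in '", dir, "': missing ",
         paste(basename(paths[missing]), collapse = ", "))
  }
  rd <- function(p) {
    x <- readLines(p, encoding = "UTF-8")
    x[nzchar(x)]
  }
  lp <- file.path(dir, paste0(name, "_links.tsv"))
  structure(
    list(
      name = name,
      one_word = rd(paths[1L]),
      two_word = rd(paths[2L]),
      more_words = rd(paths[3L]),
      first_two_words = rd(paths[4L]),
      links = if (file.exists(lp)) compile_links(read_links(lp)) else NULL
    ),
    class = "ner_lexicon"
  )
}

all_terms <- function(lex) c(lex$one_word, lex$two_word, lex$more_words)

#' Terms shared by several lexicons
#'
#' Returns the normalized terms present in at least two distinct compiled
#' lexicons. When annotating with many entity types at once, mentions of
#' these ambiguous terms are conventionally reported under an "Unknown"
#' type rather than once per lexicon.
#'
#' @param ... Two or more `ner_lexicon` objects (or a single list of them).
#' @return Character vector of normalized terms, sorted; possibly empty.
#' @export
overlap_terms <- function(...) {
  lexs <- list(...)
  if (length(lexs) == 1L && !inherits(lexs[[1L]], "ner_lexicon")) {
    lexs <- lexs[[1L]]
  }
  stopifnot(all(vapply(lexs, inherits, logical(1), "ner_lexicon")))
  if (length(lexs) < 2L) stop("need at least two lexicons")
  counts <- table(unlist(lapply(lexs, function(l) unique(all_terms(l)))))
  radix_sort(names(counts)[counts >= 2L])
}
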