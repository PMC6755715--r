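# Linking, confidence scoring and TSV serialization.

#' Link a recognized term to its URI
#'
#' Looks the normalized term up in a links table (as attached to a
#' [ner_lexicon()]): the URI of the first entry whose term equals the query
#' exactly is returned, mirroring a grep over the sorted links file that
#' keeps only the first exact match. When the same term maps to several
#' URIs, all pairs are kept in the table and the first in sorted order wins.
#'
#' @param term A single normalized term.
#' @param links Links data frame (columns `term`, `uri`), sorted, or `NULL`.
#' @return The URI string, or `NA_character_` when absent.
#' @export
link_term <- function(term, links) {
  if (is.null(links) || nrow(links) == 0L) return(NA_character_)
  i <- match(term, links$term)
  if (is.na(i)) NA_character_ else links$uri[i]
}

#' Confidence score of a mention
#'
#' `1 - 1/ln(nc)`, where `nc` is the number of characters of the recognized
#' span (end - start, spaces included). Longer mentions are assumed less
#' ambiguous, so the score increases strictly with length and is always
#' below 1. With the default minimum entity length of 3, the smallest
#' attainable score is `1 - 1/ln(3) = 0.08976` (5 decimals).
#'
#' @param nc Integer vector of span lengths in characters; must be >= 2
#'   (the logarithm is non-positive below that).
#' @return Numeric vector of scores (full precision; output writers round
#'   to 5 decimals).
#' @examples
#' round(mention_score(c(3, 14)), 5)
#' @export
mention_score <- function(nc) {
  nc <- as.numeric(nc)
  if (any(is.na(nc)) || any(nc < 2)) {
    stop("'nc' must be >= 2: 1 - 1/ln(nc) is undefined below that")
  }
  1 - 1 / log(nc)
}

write_lines_utf8 <- function(lines, file) {
  if (inherits(file, "connection")) {
    writeLines(lines, file, useBytes = TRUE)
  } else {
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeLines(enc2utf8(lines), con, useBytes = TRUE)
  }
  invisible(NULL)
}

#' Write annotations as plain TSV
#'
#' One row per annotation: `start`, `end`, `surface`, then `uri` when the
#' annotations were produced with a links table (a missing link prints as an
#' empty field), and `entity_type` when `type = TRUE`. No header; UTF-8;
#' newline-terminated rows.
#'
#' @param annotations Data frame from [annotate_text()].
#' @param file Path or connection (e.g. `stdout()`).
#' @param uri Include the URI column? Default: yes iff the annotations carry
#'   link information.
#' @param type Include the entity-type column (used when annotating with
#'   several lexicons at once)?
#' @return Invisibly, the lines written.
#' @export
write_annotations_tsv <- function(annotations, file,
                                  uri = isTRUE(attr(annotations, "linked")) ||
                                    any(!is.na(annotations$uri)),
                                  type = FALSE) {
  lines <- paste(annotations$start, annotations$end, annotations$surface,
                 sep = "\t")
  if (uri) {
    u <- ifelse(is.na(annotations$uri), "", annotations$uri)
    lines <- paste(lines, u, sep = "\t")
  }
  if (type) lines <- paste(lines, annotations$entity_type, sep = "\t")
  write_lines_utf8(lines, file)
  invisible(lines)
}

#' Read back a plain annotations TSV
#'
#' Inverse of [write_annotations_tsv()] for round-tripping: recovers
#' `start`, `end`, `surface` and (when present) `uri`.
#'
#' @param file Path to a TSV written by [write_annotations_tsv()].
#' @return Data frame.
#' @export
read_annotations_tsv <- function(file) {
  lines <- readLines(file, encoding = "UTF-8")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(parts, function(p) {
    if (length(p) >= i) p[[i]] else NA_character_
  }, character(1))
  out <- data.frame(
    start = as.integer(get(1L)),
    end = as.integer(get(2L)),
    surface = get(3L),
    stringsAsFactors = FALSE
  )
  if (any(lengths(parts) >= 4L)) {
    uri <- get(4L)
    uri[!is.na(uri) & !nzchar(uri)] <- NA_character_
    out$uri <- uri
  }
  out
}

#' Write annotations in BeCalm TSV format
#'
#' The annotation-server exchange dialect: one row per mention with the
#' fixed column order `document_id`, `section`, `start`, `end`, `score`
#' (5 decimals), `surface`, `entity_type`, `uri` (empty when unlinked).
#' No header row.
#'
#' @param annotations Data frame from [annotate_text()].
#' @param document_id Document identifier (required, non-empty).
#' @param section Section label, conventionally `"T"` (title) or `"A"`
#'   (abstract); any non-empty label is accepted.
#' @param file Path or connection.
#' @return Invisibly, the lines written.
#' @export
write_becalm_tsv <- function(annotations, document_id, section, file) {
  if (missing(document_id) || length(document_id) != 1L ||
      is.na(document_id) || !nzchar(as.character(document_id))) {
    stop("'document_id' is required for BeCalm TSV output")
  }
  if (missing(section) || length(section) != 1L || is.na(section) ||
      !nzchar(as.character(section))) {
    stop("'section' is required for BeCalm TSV output")
  }
  uri <- ifelse(is.na(annotations$uri), "", annotations$uri)
  lines <- paste(document_id, section, annotations$start, annotations$end,
                 sprintf("%.5f", annotations$score), annotations$surface,
                 annotations$entity_type, uri, sep = "\t")
  write_lines_utf8(lines, file)
  invisible(lines)
}
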