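#!/usr/bin/env Rscript
# Optional evaluation against a locally supplied gold-standard corpus
# (e.g. the human-phenotype abstracts corpus). Nothing is downloaded and no
# target value is asserted; the script reports precision/recall/F1 for span
# matching (NER) and span+URI matching (NEL).
#
# Usage:
#   Rscript scripts/evaluate_corpus.R --texts DIR --gold FILE \
#       (--ontology FILE.owl | --lexicon FILE.txt [--links FILE.tsv])
#
# --texts    directory of plain-text documents, one file per document; the
#            file name without extension is the document id
# --gold     TSV with columns: document id, start, end, uri (0-based,
#            end-exclusive character offsets; uri may be empty for NER-only)

library(lexner)

args <- commandArgs(trailingOnly = TRUE)
arg_value <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1L]
}

texts_dir <- arg_value("--texts")
gold_path <- arg_value("--gold")
if (is.null(texts_dir) || is.null(gold_path)) {
  stop("need --texts DIR and --gold FILE (see header comment)")
}

if (!is.null(arg_value("--ontology"))) {
  onto <- read_owl_terms(arg_value("--ontology"))
  lex <- ner_lexicon(onto$terms, links = onto$links, name = "gold")
} else if (!is.null(arg_value("--lexicon"))) {
  lex <- ner_lexicon(readLines(arg_value("--lexicon"), encoding = "UTF-8"),
                     links = arg_value("--links"), name = "gold")
} else {
  stop("need --ontology FILE.owl or --lexicon FILE.txt")
}

gold_lines <- strsplit(readLines(gold_path, encoding = "UTF-8"), "\t",
                       fixed = TRUE)
gold <- data.frame(
  doc = vapply(gold_lines, `[[`, character(1), 1L),
  start = as.integer(vapply(gold_lines, `[[`, character(1), 2L)),
  end = as.integer(vapply(gold_lines, `[[`, character(1), 3L)),
  uri = vapply(gold_lines, function(p) {
    if (length(p) >= 4L) p[[4L]] else ""
  }, character(1)),
  stringsAsFactors = FALSE
)

files <- Sys.glob(file.path(texts_dir, "*"))
pred <- do.call(rbind, lapply(files, function(f) {
  ann <- annotate_text(
    paste(readLines(f, encoding = "UTF-8"), collapse = "\n"), lex)
  if (nrow(ann) == 0L) return(NULL)
  data.frame(doc = sub("\\.[^.]*$", "", basename(f)),
             start = ann$start, end = ann$end,
             uri = ifelse(is.na(ann$uri), "", ann$uri),
             stringsAsFactors = FALSE)
}))

prf <- function(pred_keys, gold_keys) {
  tp <- length(intersect(pred_keys, gold_keys))
  p <- if (length(pred_keys)) tp / length(unique(pred_keys)) else 0
  r <- if (length(gold_keys)) tp / length(unique(gold_keys)) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  sprintf("P %.4f  R %.4f  F %.4f", p, r, f)
}

ner_key <- function(d) paste(d$doc, d$start, d$end)
nel_key <- function(d) paste(d$doc, d$start, d$end, d$uri)
cat("NER     ", prf(ner_key(pred), ner_key(gold)), "\n")
cat("NER+NEL ", prf(nel_key(pred), nel_key(gold)), "\n")
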