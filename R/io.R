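#' Write / read a corpus directory
#'
#' A corpus directory holds `notes.jsonl` (one JSON object per note:
#' `{"note_id","patient_id","text","labels":{name:0|1}}`),
#' `gold_spans.json` (sidecar array of gold mention spans, when present)
#' and `dictionary.tsv` (concept dictionary). All plain text.
#'
#' @param corpus A `pheno_corpus`.
#' @param dir Output directory (created if needed).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- vapply(seq_len(nrow(corpus$notes)), function(i) {
    jsonlite::toJSON(list(
      note_id = corpus$notes$note_id[i],
      patient_id = corpus$notes$patient_id[i],
      text = corpus$notes$text[i],
      labels = as.list(stats::setNames(corpus$labels[i, ],
                                       colnames(corpus$labels)))),
      auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, file.path(dir, "notes.jsonl"))
  if (!is.null(corpus$gold_spans))
    jsonlite::write_json(corpus$gold_spans,
                         file.path(dir, "gold_spans.json"),
                         dataframe = "rows", digits = NA)
  if (!is.null(corpus$dictionary))
    write_dictionary_tsv(corpus$dictionary, file.path(dir, "dictionary.tsv"))
  invisible(dir)
}

#' @rdname write_corpus
#' @return `read_corpus` returns a `pheno_corpus` (tokens recomputed with
#'   [tokenize()]).
#' @export
read_corpus <- function(dir) {
  lines <- readLines(file.path(dir, "notes.jsonl"))
  recs <- lapply(lines, jsonlite::fromJSON)
  notes <- data.frame(
    note_id = vapply(recs, `[[`, character(1), "note_id"),
    patient_id = vapply(recs, `[[`, character(1), "patient_id"),
    text = vapply(recs, `[[`, character(1), "text"),
    stringsAsFactors = FALSE)
  phen <- names(recs[[1]]$labels)
  labels <- t(vapply(recs, function(r) unlist(r$labels)[phen],
                     integer(length(phen))))
  if (length(phen) == 1L) labels <- matrix(labels, ncol = 1L)
  dimnames(labels) <- list(notes$note_id, phen)
  tokens <- lapply(notes$text, tokenize)
  names(tokens) <- notes$note_id
  gold_path <- file.path(dir, "gold_spans.json")
  gold <- if (file.exists(gold_path))
    jsonlite::read_json(gold_path, simplifyVector = TRUE) else NULL
  dict_path <- file.path(dir, "dictionary.tsv")
  dict <- if (file.exists(dict_path)) read_dictionary_tsv(dict_path) else NULL
  structure(list(notes = notes, tokens = tokens, labels = labels,
                 gold_spans = gold, dictionary = dict, config = NULL),
            class = "pheno_corpus")
}
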