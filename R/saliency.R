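#' Gradient word saliency
#'
#' Saliency of each token position as the L2 norm of the gradient of the
#' loss `L(target, y)` with respect to that position's embedding vector
#' (positions are scored independently, so duplicate tokens at different
#' positions can score differently). The default target label is 1: the
#' score measures how strongly the position drives the loss of a positive
#' call.
#'
#' @param model Trained `conv_model`.
#' @param ids Encoded note.
#' @param target Target label for the loss (default 1).
#' @return Numeric vector of non-negative scores, one per (unpadded) token.
#' @export
word_saliency <- function(model, ids, target = 1) {
  fw <- cnn_forward(model, ids)
  bw <- cnn_backward(model, fw, target, mask = NULL, want_dx = TRUE)
  sqrt(rowSums(bw$dX^2))[seq_len(fw$n_real)]
}

#' Gradient phrase saliency
#'
#' For each filter `j` the phrase saliency is `|dL(target, y)/d c_hat_j|`,
#' the magnitude of the loss gradient with respect to the filter's pooled
#' feature-map value, attributed to the pooled (argmax) token window. It is
#' computed by the chain rule through the sigmoid output
#' (`dL/dc_hat_j = (y - target) * w_out_j`); for this architecture and
#' target 1 it therefore equals `(1 - y) * |w_out_j|`.
#'
#' @param model Trained `conv_model`.
#' @param ids Encoded note.
#' @param tokens Optional raw tokens (to attach phrase text).
#' @param note_id Optional note identifier carried into the records.
#' @param target Target label for the loss (default 1).
#' @return data.frame(note_id, filter, width, start, end, phrase, score):
#'   one record per filter, windows as 1-based inclusive token positions.
#'   Windows lying entirely in right-padding are dropped, as are filters
#'   whose feature map is identically zero after the ReLU: a dead map has
#'   no maximally-activated window (the argmax is an arbitrary tie), so
#'   there is no phrase to attribute its gradient to.
#' @export
phrase_saliency <- function(model, ids, tokens = NULL, note_id = NA_character_,
                            target = 1) {
  fw <- cnn_forward(model, ids)
  delta <- fw$y - target         # dL/dlogit
  m <- model$config$n_filters
  out <- list()
  off <- 0L
  for (h in model$config$widths) {
    cache <- fw$caches[[as.character(h)]]
    score <- abs(delta * model$w_out[off + seq_len(m)])  # |dL/d c_hat|
    start <- cache$am
    keep <- start <= fw$n_real &            # exclude all-padding windows
      fw$z[off + seq_len(m)] > 0            # and dead feature maps
    end <- pmin(start + h - 1L, fw$n_real)
    phrase <- if (!is.null(tokens))
      vapply(seq_along(start), function(j)
        paste(tokens[start[j]:end[j]], collapse = " "), character(1))
    else NA_character_
    out[[as.character(h)]] <- data.frame(
      note_id = note_id, filter = off + seq_len(m), width = h,
      start = start, end = end, phrase = phrase, score = score,
      stringsAsFactors = FALSE)[keep, , drop = FALSE]
    off <- off + m
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Loss as a function of the pooled vector
#'
#' Evaluates `L(target, sigma(w_out . z + b_out))` for an arbitrary pooled
#' vector `z` — the downstream half of the network, used to check phrase
#' saliency against central finite differences on `z`.
#'
#' @param model A `conv_model`.
#' @param z Pooled feature vector.
#' @param target Label in `{0, 1}`.
#' @return The negative log-likelihood.
#' @export
cnn_loss_from_z <- function(model, z, target = 1) {
  nll_from_logit(sum(model$w_out * z) + model$b_out, target)
}

#' Most salient phrases of one note
#'
#' Takes each filter's phrase-saliency record, keeps the best-scoring
#' record per distinct token window, sorts by decreasing score (ties by
#' lower start index, then smaller width) and truncates to `top_k`.
#'
#' @inheritParams phrase_saliency
#' @param top_k Number of records to keep (>= 1).
#' @return data.frame of saliency records.
#' @export
note_top_phrases <- function(model, ids, tokens = NULL, top_k = 5L,
                             note_id = NA_character_, target = 1) {
  if (top_k < 1L) stop("top_k must be >= 1")
  rec <- phrase_saliency(model, ids, tokens, note_id, target)
  if (nrow(rec) == 0L) return(rec)
  key <- paste(rec$start, rec$width)
  rec <- rec[order(-rec$score, rec$start, rec$width), , drop = FALSE]
  rec <- rec[!duplicated(paste(rec$start, rec$width)), , drop = FALSE]
  head(rec, top_k)
}

#' Globally most salient phrases over a corpus
#'
#' Iterates over notes, pools each note's top phrase-saliency records,
#' collapses duplicate phrases (normalized to lowercase with single
#' spaces) keeping the maximum score, and returns the `top_k` ranking —
#' the phrase-dictionary-shaped view of what the model has learned.
#'
#' Ranking salient phrases *for* a phenotype is meaningful on notes that
#' exhibit it: on a confidently negative note the loss toward target 1 is
#' large and its gradient points at arbitrary background windows. Callers
#' therefore typically pass the predicted-positive subset (the pipeline
#' default); the function itself ranks whatever notes it is given.
#'
#' @param model Trained `conv_model`.
#' @param ids_list List of encoded notes.
#' @param tokens_list Parallel list of raw token vectors.
#' @param note_ids Note identifiers (defaults to names of `ids_list`).
#' @param top_k Length of the global ranking.
#' @param per_note_k Records pooled per note before global dedup.
#' @param target Target label (default 1).
#' @return data.frame(rank, phrase, score, note_id, start, width).
#' @export
global_top_phrases <- function(model, ids_list, tokens_list,
                               note_ids = NULL, top_k = 20L,
                               per_note_k = 10L, target = 1) {
  if (length(ids_list) == 0L) stop("empty corpus")
  if (is.null(note_ids))
    note_ids <- names(ids_list) %||% as.character(seq_along(ids_list))
  recs <- do.call(rbind, lapply(seq_along(ids_list), function(i)
    note_top_phrases(model, ids_list[[i]], tokens_list[[i]],
                     top_k = per_note_k, note_id = note_ids[i],
                     target = target)))
  if (is.null(recs) || nrow(recs) == 0L)
    return(data.frame(rank = integer(), phrase = character(),
                      score = numeric(), note_id = character(),
                      start = integer(), width = integer()))
  recs$phrase_norm <- tolower(gsub("\\s+", " ", trimws(recs$phrase)))
  recs <- recs[order(-recs$score, recs$phrase_norm, recs$start), ,
               drop = FALSE]
  recs <- recs[!duplicated(recs$phrase_norm), , drop = FALSE]
  recs <- head(recs, top_k)
  data.frame(rank = seq_len(nrow(recs)), phrase = recs$phrase_norm,
             score = recs$score, note_id = recs$note_id,
             start = recs$start, width = recs$width,
             stringsAsFactors = FALSE)
}

#' Highlight salient windows in the original text
#'
#' Wraps the character spans of salient token windows in markers
#' (`[[ ... |score]]`), merging overlapping windows into one region that
#' keeps the maximum score. Character offsets are recovered by re-scanning
#' the original text with the tokenizer's pattern, so markers land in the
#' untokenized note.
#'
#' @param text The original note text.
#' @param records Saliency records for this note (need `start`, `end`,
#'   `score` in token positions).
#' @return The annotated text (character scalar).
#' @export
highlight_note <- function(text, records) {
  if (is.null(records) || nrow(records) == 0L) return(text)
  offs <- tokenize_offsets(text)
  iv <- merge_windows(records)
  iv <- iv[iv$start <= nrow(offs), , drop = FALSE]
  if (nrow(iv) == 0L) return(text)
  iv$end <- pmin(iv$end, nrow(offs))
  out <- text
  for (i in rev(seq_len(nrow(iv)))) {  # right to left keeps offsets valid
    cs <- offs$start[iv$start[i]]
    ce <- offs$end[iv$end[i]]
    out <- paste0(substr(out, 1L, cs - 1L),
                  "[[", substr(out, cs, ce),
                  sprintf("|%.4g]]", iv$score[i]),
                  substr(out, ce + 1L, nchar(out)))
  }
  out
}

# Merge overlapping/adjacent-by-overlap token windows; union span, max
# score; returned ordered by start.
merge_windows <- function(records) {
  r <- records[order(records$start, records$end), , drop = FALSE]
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(r))) {
    if (is.null(cur)) {
      cur <- list(start = r$start[i], end = r$end[i], score = r$score[i])
    } else if (r$start[i] <= cur$end) {
      cur$end <- max(cur$end, r$end[i])
      cur$score <- max(cur$score, r$score[i])
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- list(start = r$start[i], end = r$end[i], score = r$score[i])
    }
  }
  out[[length(out) + 1L]] <- cur
  do.call(rbind, lapply(out, as.data.frame))
}

#' Write saliency artifacts
#'
#' `write_saliency_json` writes records as a JSON array of
#' `{note_id, phrase, start, end, width, score}`; `write_ranking_tsv`
#' writes a global ranking as `rank phrase score note_id` TSV;
#' `write_highlight_html` renders highlighted notes as a minimal HTML page
#' with `<mark>` spans.
#'
#' @param records Saliency records.
#' @param path Output path.
#' @export
write_saliency_json <- function(records, path) {
  cols <- intersect(c("note_id", "phrase", "start", "end", "width", "score"),
                    names(records))
  jsonlite::write_json(records[, cols], path, dataframe = "rows",
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_saliency_json
#' @param ranking A [global_top_phrases()] data.frame.
#' @export
write_ranking_tsv <- function(ranking, path) {
  utils::write.table(ranking[, c("rank", "phrase", "score", "note_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_saliency_json
#' @param texts Named character vector of note texts.
#' @param records_list Named list of per-note saliency records.
#' @export
write_highlight_html <- function(texts, records_list, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  body <- vapply(names(texts), function(id) {
    marked <- highlight_note(esc(texts[[id]]), records_list[[id]])
    marked <- gsub("\\[\\[", "<mark>", marked)
    marked <- gsub("\\|([0-9.eE+-]+)\\]\\]",
                   "<sup>\\1</sup></mark>", marked)
    paste0("<h3>", esc(id), "</h3><p>", marked, "</p>")
  }, character(1))
  writeLines(c("<!DOCTYPE html><html><body>", body, "</body></html>"),
             path)
  invisible(path)
}
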