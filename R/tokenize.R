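#' Tokenize clinical text
#'
#' Lowercases and splits on any run of non-alphanumeric characters. Numeric
#' tokens are kept (ejection fractions, BMI values and similar matter for
#' phenotyping); empty tokens are dropped. Deterministic.
#'
#' @param text A character scalar (or vector; vectors are tokenized
#'   element-wise and returned as a list).
#' @return A character vector of tokens (or a list of such vectors).
#' @examples
#' tokenize("EF 20-30%.")  # c("ef", "20", "30")
#' @export
tokenize <- function(text) {
  if (length(text) != 1L) return(lapply(text, tokenize))
  parts <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  parts[nzchar(parts)]
}

# Token char spans in the original text (for highlight rendering).
# Returns a data.frame(token, start, end) with 1-based inclusive character
# offsets, aligned with tokenize(text).
tokenize_offsets <- function(text) {
  m <- gregexpr("[a-z0-9]+", tolower(text))[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(), start = integer(), end = integer()))
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  data.frame(token = substring(tolower(text), start, start + len - 1L),
             start = start, end = start + len - 1L,
             stringsAsFactors = FALSE)
}

PAD_INDEX <- 1L
OOV_INDEX <- 2L
PAD_TOKEN <- "<pad>"
OOV_TOKEN <- "<oov>"

#' Build a vocabulary from a tokenized corpus
#'
#' Tokens with frequency at least `min_count` receive indices; all others
#' encode to the out-of-vocabulary index. Index order is deterministic:
#' frequency descending, ties broken lexicographically. Indices 1 and 2 are
#' reserved for the padding and out-of-vocabulary tokens.
#'
#' @param token_lists List of character vectors (one per note), or a single
#'   character vector.
#' @param min_count Minimum corpus frequency for a token to be indexed.
#' @return An object of class `pheno_vocab` with elements `itos`
#'   (index to token), `counts` (corpus frequency per indexed token) and
#'   `min_count`.
#' @export
build_vocab <- function(token_lists, min_count = 1L) {
  if (is.character(token_lists)) token_lists <- list(token_lists)
  all_tokens <- unlist(token_lists, use.names = FALSE)
  if (length(all_tokens) == 0L) stop("corpus is empty; cannot build a vocabulary")
  tab <- table(all_tokens)
  keep <- tab[tab >= min_count]
  if (length(keep) == 0L) stop("min_count = ", min_count, " excludes every token")
  ord <- order(-as.integer(keep), names(keep), method = "radix")
  itos <- c(PAD_TOKEN, OOV_TOKEN, names(keep)[ord])
  structure(list(itos = itos,
                 counts = c(0L, 0L, as.integer(keep)[ord]),
                 min_count = as.integer(min_count)),
            class = "pheno_vocab")
}

#' @export
print.pheno_vocab <- function(x, ...) {
  cat("<pheno_vocab> ", length(x$itos), " entries (incl. <pad>, <oov>), min_count = ",
      x$min_count, "\n", sep = "")
  invisible(x)
}

vocab_size <- function(vocab) length(vocab$itos)

#' Encode tokens as vocabulary indices
#'
#' Unseen tokens map to the out-of-vocabulary index; encoding never fails.
#'
#' @param tokens Character vector of tokens.
#' @param vocab A `pheno_vocab`.
#' @return Integer vector of indices into `vocab$itos`.
#' @export
encode_tokens <- function(tokens, vocab) {
  idx <- match(tokens, vocab$itos)
  idx[is.na(idx)] <- OOV_INDEX
  idx
}

# Right-pad an index vector with PAD up to length `min_len`.
pad_ids <- function(ids, min_len) {
  if (length(ids) >= min_len) return(ids)
  c(ids, rep(PAD_INDEX, min_len - length(ids)))
}
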