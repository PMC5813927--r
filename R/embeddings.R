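#' Train word embeddings by skip-gram with negative sampling
#'
#' Pre-trains k-dimensional word vectors on a tokenized corpus so that
#' words occurring in similar contexts (misspellings, synonyms,
#' abbreviations of the same clinical term) end up with similar embeddings.
#' The trainer is an in-package skip-gram-with-negative-sampling
#' implementation (compiled, single-threaded, deterministic given the
#' seed): uniform input initialization, unigram^0.75 negative-sampling
#' distribution, dynamic window, linearly decaying learning rate.
#' With `epochs = 0` the returned table equals its random initialization.
#'
#' @param tokens_list List of token vectors (typically all notes of a
#'   corpus — pre-training uses text only, never labels).
#' @param vocab A [build_vocab()] vocabulary.
#' @param k Embedding dimension.
#' @param window Maximum context window half-width.
#' @param negatives Negative samples per (center, context) pair.
#' @param epochs Passes over the corpus.
#' @param lr Initial learning rate.
#' @param seed Integer seed.
#' @return A numeric matrix (vocabulary size x k) with `vocab$itos` as row
#'   names; the `<pad>` row is all-zero.
#' @export
train_embeddings <- function(tokens_list, vocab, k = 50L, window = 5L,
                             negatives = 5L, epochs = 5L, lr = 0.025,
                             seed = 1L) {
  if (k <= 0) stop("k must be > 0")
  if (window <= 0) stop("window must be > 0")
  ids <- lapply(tokens_list, encode_tokens, vocab = vocab)
  fit <- cpp_sgns_train(ids, vocab_size(vocab), as.integer(k),
                        as.integer(window), as.integer(negatives),
                        as.integer(epochs), lr, as.integer(seed))
  emb <- fit$input
  rownames(emb) <- vocab$itos
  emb[PAD_INDEX, ] <- 0
  if (!all(is.finite(emb))) stop("non-finite embedding values")
  emb
}

#' Cosine similarity between two embedding rows
#' @param emb Embedding matrix with token row names.
#' @param a,b Tokens or row indices.
#' @return Cosine similarity in \[-1, 1\].
#' @export
cosine_sim <- function(emb, a, b) {
  va <- emb[a, ]; vb <- emb[b, ]
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

#' Word2vec text format I/O
#'
#' Standard text format: a header line `"<count> <dim>"`, then one
#' `"token v1 ... vk"` line per word. Values round-trip to at least six
#' decimals.
#'
#' @param emb Embedding matrix with token row names.
#' @param path File path.
#' @return `read_word2vec` returns the embedding matrix with token row
#'   names.
#' @export
write_word2vec <- function(emb, path) {
  if (is.null(rownames(emb)))
    stop("embedding matrix needs token row names")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(emb), ncol(emb)), con)
  vals <- formatC(emb, format = "g", digits = 17)  # full double precision
  writeLines(paste(rownames(emb), apply(vals, 1, paste, collapse = " ")),
             con)
  invisible(path)
}

#' @rdname write_word2vec
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2L) stop("malformed word2vec header")
  n <- as.integer(hdr[1]); k <- as.integer(hdr[2])
  if (is.na(n) || is.na(k)) stop("malformed word2vec header")
  if (length(lines) - 1L != n)
    stop("header promises ", n, " rows, file has ", length(lines) - 1L)
  parts <- strsplit(trimws(lines[-1]), "\\s+")
  bad <- which(lengths(parts) != k + 1L)
  if (length(bad) > 0L)
    stop("row ", bad[1], " has ", lengths(parts)[bad[1]] - 1L,
         " values, expected ", k)
  emb <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(k)))
  if (k == 1L) emb <- matrix(emb, ncol = 1L)
  rownames(emb) <- vapply(parts, `[`, character(1), 1L)
  if (any(is.na(emb))) stop("non-numeric embedding value")
  emb
}

#' Attach an external embedding table to a vocabulary
#'
#' Maps a word2vec-format table onto a vocabulary: known tokens take their
#' pre-trained vectors, unknown tokens are drawn from a small seeded
#' uniform, `<pad>` stays zero.
#'
#' @param emb Matrix from [read_word2vec()].
#' @param vocab A [build_vocab()] vocabulary.
#' @param seed Seed for rows absent from `emb`.
#' @return Matrix aligned with `vocab$itos`.
#' @export
align_embeddings <- function(emb, vocab, seed = 1L) {
  k <- ncol(emb)
  out <- with_seed(seed,
    matrix(runif(vocab_size(vocab) * k, -0.5, 0.5) / k,
           vocab_size(vocab), k))
  hit <- match(vocab$itos, rownames(emb))
  out[!is.na(hit), ] <- emb[hit[!is.na(hit)], , drop = FALSE]
  rownames(out) <- vocab$itos
  out[PAD_INDEX, ] <- 0
  out
}
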