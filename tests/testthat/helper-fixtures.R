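# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk.

tiny_vocab <- function(n_tokens = 10L) {
  structure(list(itos = c("<pad>", "<oov>", sprintf("t%02d", seq_len(n_tokens))),
                 counts = rep(1L, n_tokens + 2L), min_count = 1L),
            class = "pheno_vocab")
}

# A random small conv_model. Notes fed to it should avoid duplicate
# windows (see random_note) so that max-pooling has no exact ties, which
# would make finite differences one-sided.
random_small_cnn <- function(k = 3L, n_tokens = 30L, widths = NULL,
                             n_filters = NULL) {
  vocab <- tiny_vocab(n_tokens)
  if (is.null(widths)) widths <- sort(sample(1:3, sample(1:3, 1)))
  if (is.null(n_filters)) n_filters <- sample(2:4, 1)
  emb <- matrix(rnorm(length(vocab$itos) * k), ncol = k,
                dimnames = list(vocab$itos, NULL))
  emb[1, ] <- 0
  cfg <- cnn_config(widths = widths, n_filters = n_filters, dropout = 0,
                    seed = 1)
  filters <- stats::setNames(lapply(widths, function(h)
    list(W = matrix(rnorm(n_filters * h * k), n_filters, h * k),
         b = rnorm(n_filters), h = h)), as.character(widths))
  structure(list(config = cfg, emb = emb, vocab = vocab, filters = filters,
                 w_out = rnorm(length(widths) * n_filters),
                 b_out = rnorm(1), threshold = 0.5, history = NULL),
            class = "conv_model")
}

# Distinct tokens => all convolution windows are distinct almost surely.
random_note <- function(model, len = 8L) {
  sample(3:nrow(model$emb), len, replace = FALSE)
}

# Central finite difference of the CNN loss wrt the embedding vector used
# at one *position* (the position gets a private copy of its token's row).
fd_position_grad <- function(model, ids, i, target = 1, eps = 1e-6) {
  k <- ncol(model$emb)
  vapply(seq_len(k), function(c) {
    mp <- model
    mp$emb <- rbind(model$emb, model$emb[ids[i], , drop = FALSE])
    idp <- ids
    idp[i] <- nrow(mp$emb)
    mp$emb[nrow(mp$emb), c] <- mp$emb[nrow(mp$emb), c] + eps
    lp <- cnn_loss(mp, idp, target)
    mp$emb[nrow(mp$emb), c] <- mp$emb[nrow(mp$emb), c] - 2 * eps
    ln <- cnn_loss(mp, idp, target)
    (lp - ln) / (2 * eps)
  }, numeric(1))
}

# Small single-phenotype corpus for pipeline tests.
small_pipeline_corpus <- function(n = 120L, prevalence = 0.3,
                                  note_length = 80, seed = 7L,
                                  misspelling_rate = 0,
                                  negated_decoy_rate = 0.3) {
  generate_corpus(synth_config(
    n_patients = n, notes_per_patient_mean = 1.2,
    phenotypes = list(phenotype_spec(
      "alcohol_abuse", prevalence,
      c("alcohol abuse", "etoh abuse"),
      list("alcohol abuse" = "alcoholism"))),
    vocab_size = 300L, note_length_mean = note_length,
    note_length_sd = note_length / 8,
    misspelling_rate = misspelling_rate,
    negated_decoy_rate = negated_decoy_rate, seed = seed))
}

brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}
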