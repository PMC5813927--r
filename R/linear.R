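#' n-gram featurization
#'
#' Counts every contiguous token n-gram for n in `[n_min, n_max]` (n_max up
#' to 5; longer phrases make the counts too sparse to be useful). The
#' feature vocabulary is built on a training corpus — most frequent n-grams
#' first, capped at `max_features`, ties broken lexicographically — and then
#' applied to any corpus; unseen n-grams are dropped.
#'
#' `n_min = n_max = 1` is the bag-of-words representation
#' `x = sum_i delta(f_i)`.
#'
#' @param tokens_list List of token vectors (training corpus for
#'   `ngram_vocab`, any corpus for `featurize_ngrams`).
#' @param n_min,n_max Inclusive n-gram length range, `1 <= n_min <= n_max <= 5`.
#' @param max_features Cap on vocabulary size (default 200000).
#' @return `ngram_vocab`: character vector of feature strings.
#'   `featurize_ngrams`: sparse `dgCMatrix` (notes x features).
#' @export
ngram_vocab <- function(tokens_list, n_min = 1L, n_max = 1L,
                        max_features = 200000L) {
  check_ngram_range(n_min, n_max)
  grams <- unlist(lapply(tokens_list, note_ngrams, n_min, n_max),
                  use.names = FALSE)
  if (length(grams) == 0L) return(character(0))
  tab <- table(grams)
  ord <- order(-as.integer(tab), names(tab), method = "radix")
  head(names(tab)[ord], max_features)
}

#' @rdname ngram_vocab
#' @param vocab Feature vocabulary from `ngram_vocab` (built on training
#'   notes only, to avoid leakage).
#' @export
featurize_ngrams <- function(tokens_list, vocab, n_min = 1L, n_max = 1L) {
  check_ngram_range(n_min, n_max)
  n <- length(tokens_list)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(n)) {
    g <- note_ngrams(tokens_list[[i]], n_min, n_max)
    j <- match(g, vocab)
    j <- j[!is.na(j)]
    if (length(j) == 0L) next
    tab <- table(j)
    ii <- c(ii, rep.int(i, length(tab)))
    jj <- c(jj, as.integer(names(tab)))
    xx <- c(xx, as.numeric(tab))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, length(vocab)),
                       dimnames = list(names(tokens_list), vocab))
}

check_ngram_range <- function(n_min, n_max) {
  if (!(n_min >= 1L && n_min <= n_max && n_max <= 5L))
    stop("need 1 <= n_min <= n_max <= 5")
}

# All contiguous n-grams of a note for each n in [n_min, n_max]; a note of
# length L contributes exactly max(L - n + 1, 0) n-grams per n.
note_ngrams <- function(tokens, n_min, n_max) {
  L <- length(tokens)
  out <- character(0)
  for (n in n_min:n_max) {
    if (L < n) next
    if (n == 1L) { out <- c(out, tokens); next }
    m <- vapply(0:(n - 1L), function(o) tokens[(1L + o):(L - n + 1L + o)],
                character(L - n + 1L))
    if (L - n + 1L == 1L) m <- matrix(m, nrow = 1L)
    out <- c(out, apply(m, 1L, paste, collapse = " "))
  }
  out
}

#' Logistic regression by full-batch gradient descent
#'
#' Minimizes the L2-regularized negative log-likelihood of
#' `y = sigma(w . x + b)` with a fixed step size — deliberately plain
#' deterministic gradient descent (no line search, no stochastic order),
#' so that descent and symmetry properties are directly assertable. The
#' bias is not penalized.
#'
#' @param x Feature matrix (dense or `dgCMatrix`), rows = notes.
#' @param y Binary labels.
#' @param l2 L2 penalty on the weights (default 1e-4).
#' @param lr Step size; `NULL` (default) uses the guaranteed-descent step
#'   `1/L` with `L = mean_i ||x_i||^2 / 4 + l2`, the standard smoothness
#'   bound of the regularized logistic loss (computed from the data before
#'   iterating, so the step is still fixed and deterministic).
#' @param epochs Number of full-batch steps.
#' @return Object of class `linear_model`: list(w, b, loss_history, ...).
#' @export
train_logistic <- function(x, y, l2 = 1e-4, lr = NULL, epochs = 5000L) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes")
  n <- nrow(x); d <- ncol(x)
  if (is.null(lr)) {
    lips <- mean(Matrix::rowSums(x^2)) / 4 + l2 + 1e-12
    lr <- 1 / lips
  }
  w <- numeric(d); b <- 0
  loss_history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    s <- as.numeric(x %*% w) + b
    p <- sigmoid(s)
    loss_history[e] <- mean(nll_from_logit(s, y)) + l2 / 2 * sum(w^2)
    g <- as.numeric(Matrix::crossprod(x, p - y)) / n + l2 * w
    gb <- mean(p - y)
    w <- w - lr * g
    b <- b - lr * gb
  }
  structure(list(w = w, b = b, l2 = l2, lr = lr, epochs = epochs,
                 features = colnames(x), loss_history = loss_history),
            class = "linear_model")
}

#' @export
predict.linear_model <- function(object, newdata, ...) {
  sigmoid(as.numeric(newdata %*% object$w) + object$b)
}

#' Multinomial naive Bayes on count features
#'
#' Laplace-smoothed multinomial model; posteriors are computed in log space
#' and are finite for any `alpha > 0`.
#'
#' @param x Non-negative count matrix.
#' @param y Binary labels.
#' @param alpha Laplace smoothing (> 0).
#' @return Object of class `nb_model`.
#' @export
train_naive_bayes <- function(x, y, alpha = 1) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (any(x < 0)) stop("naive Bayes needs non-negative count features")
  y <- as.integer(y)
  d <- ncol(x)
  log_theta <- matrix(0, 2, d)
  log_prior <- numeric(2)
  for (cls in 0:1) {
    rows <- which(y == cls)
    cnt <- Matrix::colSums(x[rows, , drop = FALSE])
    log_theta[cls + 1L, ] <- log(cnt + alpha) - log(sum(cnt) + alpha * d)
    log_prior[cls + 1L] <- log(length(rows) / length(y))
  }
  structure(list(log_theta = log_theta, log_prior = log_prior,
                 features = colnames(x)),
            class = "nb_model")
}

#' @export
predict.nb_model <- function(object, newdata, ...) {
  s0 <- as.numeric(newdata %*% object$log_theta[1, ]) + object$log_prior[1]
  s1 <- as.numeric(newdata %*% object$log_theta[2, ]) + object$log_prior[2]
  m <- pmax(s0, s1)
  exp(s1 - m) / (exp(s0 - m) + exp(s1 - m))  # P(y = 1 | x)
}

#' Random forest with gini importance
#'
#' CART-style trees on bootstrap samples with gini-impurity splits,
#' delegated to `ranger` (seeded, single-threaded for determinism);
#' per-feature importance is the normalized total impurity decrease.
#'
#' @param x Feature matrix.
#' @param y Binary labels (needs at least 2 samples per class).
#' @param n_trees Number of trees.
#' @param max_depth Depth cap; 0 = unlimited.
#' @param seed Integer seed.
#' @return Object of class `forest_model` with `$importance` (normalized,
#'   sums to 1 when any split exists).
#' @export
train_forest <- function(x, y, n_trees = 200L, max_depth = 0L, seed = 1L) {
  y <- as.integer(y)
  if (min(table(factor(y, levels = 0:1))) < 2L)
    stop("need at least 2 samples per class")
  df <- as.data.frame(as.matrix(x))
  colnames(df) <- paste0("f", seq_len(ncol(df)))  # ranger-safe names
  df$.y <- factor(y, levels = 0:1)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = n_trees, max.depth = max_depth,
                        importance = "impurity", probability = TRUE,
                        seed = seed, num.threads = 1L)
  imp <- fit$variable.importance
  imp[imp < 0] <- 0
  total <- sum(imp)
  importance <- if (total > 0) imp / total else imp * 0
  names(importance) <- colnames(x)
  structure(list(fit = fit, importance = importance,
                 features = colnames(x)),
            class = "forest_model")
}

#' @export
predict.forest_model <- function(object, newdata, ...) {
  df <- as.data.frame(as.matrix(newdata))
  colnames(df) <- paste0("f", seq_len(ncol(df)))
  predict(object$fit, data = df, num.threads = 1L)$predictions[, "1"]
}

#' Rank features by gini importance
#'
#' Global ranking of features by the forest's normalized impurity decrease;
#' with `present` given, the per-document variant — the global ranking
#' restricted to the features occurring in that document.
#'
#' @param model A `forest_model`.
#' @param present Optional character vector of features present in one
#'   document.
#' @return data.frame(feature, importance), ordered by decreasing
#'   importance; empty when no split produced any importance.
#' @export
rank_features_gini <- function(model, present = NULL) {
  imp <- model$importance
  if (length(imp) == 0L || sum(imp) == 0)
    return(data.frame(feature = character(), importance = numeric()))
  if (!is.null(present)) imp <- imp[names(imp) %in% present]
  ord <- order(-imp, names(imp), method = "radix")
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Pooled-embedding logistic regression
#'
#' The degenerate baseline: a single shared weight vector `w` scores a note
#' as `(1/n) sum_i w . x_i` (mean pooling; notes of any length get a
#' length-normalized score, so a note repeated twice scores identically) or
#' `max_i w . x_i` (max pooling), followed by a sigmoid. In long notes the
#' averaged signal of a few indicative tokens is smoothed out, which is
#' exactly the failure mode this baseline demonstrates.
#'
#' @param ids_list List of encoded notes (integer vectors).
#' @param y Binary labels.
#' @param emb Embedding matrix (vocab x k).
#' @param pool "mean" or "max".
#' @param l2,lr,epochs Gradient-descent hyperparameters.
#' @return Object of class `embed_pool_model`.
#' @export
train_embed_pool <- function(ids_list, y, emb, pool = c("mean", "max"),
                             l2 = 1e-4, lr = 0.5, epochs = 200L) {
  pool <- match.arg(pool)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("training set must contain both classes")
  if (pool == "mean") {
    x <- t(vapply(ids_list, function(ids) colMeans(emb[ids, , drop = FALSE]),
                  numeric(ncol(emb))))
    lm <- train_logistic(x, y, l2 = l2, lr = lr, epochs = epochs)
    return(structure(list(w = lm$w, b = lm$b, pool = pool, emb = emb,
                          loss_history = lm$loss_history),
                     class = "embed_pool_model"))
  }
  # max pooling: argmax token depends on w, so iterate GD directly.
  # max_i w.x_i only depends on which vocabulary rows occur in the note,
  # so project the whole vocabulary once per epoch (|V| x 1 matvec) and
  # look scores up per note instead of gathering embedding rows.
  n <- length(ids_list)
  k <- ncol(emb)
  w <- numeric(k); b <- 0
  loss_history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    v <- as.numeric(emb %*% w)
    gw <- numeric(k); gb <- 0; loss <- 0
    for (i in seq_len(n)) {
      sc <- v[ids_list[[i]]]
      j <- which.max(sc)
      s <- sc[j] + b
      p <- sigmoid(s)
      loss <- loss + nll_from_logit(s, y[i])
      gw <- gw + (p - y[i]) * emb[ids_list[[i]][j], ]
      gb <- gb + (p - y[i])
    }
    loss_history[e] <- loss / n + l2 / 2 * sum(w^2)
    w <- w - lr * (gw / n + l2 * w)
    b <- b - lr * gb / n
  }
  structure(list(w = w, b = b, pool = pool, emb = emb,
                 loss_history = loss_history),
            class = "embed_pool_model")
}

#' @export
predict.embed_pool_model <- function(object, ids_list, ...) {
  v <- as.numeric(object$emb %*% object$w)
  vapply(ids_list, function(ids) {
    s <- if (object$pool == "mean") mean(v[ids]) else max(v[ids])
    sigmoid(s + object$b)
  }, numeric(1))
}

#' Save / load a linear model as JSON
#' @param model A `linear_model`.
#' @param path File path.
#' @export
write_linear_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_linear_model
#' @export
read_linear_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "linear_model")
}
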