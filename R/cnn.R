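#' CNN configuration
#'
#' A multi-width convolutional text classifier: each note is embedded, a
#' bank of `n_filters` filters per convolution width `h` computes
#' `c_i = ReLU(w . x_{i:i+h-1} + b)` over every token window, each feature
#' map is max-over-time pooled to its single most predictive value, the
#' pooled values are concatenated into `z`, and the prediction is
#' `y = sigma(w_out . z + b_out)`. One model is trained per phenotype by
#' minimizing the negative conditional log-likelihood.
#'
#' @param widths Set of convolution widths, a subset of 1..5 (phrases of
#'   one to five words).
#' @param n_filters Feature maps per width.
#' @param dropout Dropout rate on `z` during training.
#' @param l2 Weight decay on filter and output weights (biases and
#'   embeddings unpenalized). Shrinks filters whose pooled value is
#'   constant across notes (those are redundant with the output bias and
#'   would otherwise pollute saliency rankings).
#' @param lr Adam learning rate for filters and output layer.
#' @param lr_emb SGD learning rate for fine-tuned embedding rows.
#' @param epochs Maximum training epochs.
#' @param batch_size Mini-batch size (set `>= n` for full-batch descent).
#' @param seed Integer seed governing initialization, shuffling, dropout.
#' @param fine_tune Fine-tune embeddings during training?
#' @param patience Early-stopping patience on validation F1.
#' @param optimizer "adam" (default) or plain "sgd".
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(widths = 1:5, n_filters = 32L, dropout = 0.5,
                       l2 = 5e-4, lr = 1e-3, lr_emb = 0.01, epochs = 15L,
                       batch_size = 32L, seed = 1L, fine_tune = TRUE,
                       patience = 3L, optimizer = c("adam", "sgd")) {
  widths <- sort(unique(as.integer(widths)))
  if (length(widths) == 0L || any(widths < 1L | widths > 5L))
    stop("widths must be a non-empty subset of 1..5")
  if (n_filters < 1L) stop("need at least one filter per width")
  stopifnot(dropout >= 0, dropout < 1)
  structure(list(widths = widths, n_filters = as.integer(n_filters),
                 dropout = dropout, l2 = l2, lr = lr, lr_emb = lr_emb,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), fine_tune = isTRUE(fine_tune),
                 patience = as.integer(patience),
                 optimizer = match.arg(optimizer)),
            class = "cnn_config")
}

# Initialize a conv_model. Filter weights ~ N(0, 2/(h*k)) (He), biases 0,
# output weights ~ N(0, 0.01), all drawn from the current RNG state.
cnn_init <- function(emb, vocab, config) {
  k <- ncol(emb)
  filters <- list()
  for (h in config$widths) {
    m <- config$n_filters
    filters[[as.character(h)]] <- list(
      W = matrix(rnorm(m * h * k, 0, sqrt(2 / (h * k))), m, h * k),
      b = numeric(m), h = h)
  }
  m_total <- length(config$widths) * config$n_filters
  structure(list(config = config, emb = emb, vocab = vocab,
                 filters = filters,
                 w_out = rnorm(m_total, 0, 0.1), b_out = 0,
                 threshold = 0.5, history = NULL),
            class = "conv_model")
}

#' @export
print.conv_model <- function(x, ...) {
  cat("<conv_model> widths {", paste(x$config$widths, collapse = ","),
      "} x ", x$config$n_filters, " filters, k = ", ncol(x$emb),
      ", threshold = ", signif(x$threshold, 4), "\n", sep = "")
  invisible(x)
}

#' CNN forward pass
#'
#' Computes all feature maps, the max-over-time pooled vector `z` (argmax
#' ties broken by lowest window index), and the output probability. Notes
#' shorter than the largest width are right-padded with the zero `<pad>`
#' embedding.
#'
#' @param model A `conv_model`.
#' @param ids Integer vector of encoded tokens.
#' @return list(y, logit, z, n_real, per-width cache with argmax indices,
#'   ReLU activity flags and the argmax input windows).
#' @export
cnn_forward <- function(model, ids) {
  cfg <- model$config
  n_real <- length(ids)
  ids <- pad_ids(ids, max(cfg$widths))
  X <- model$emb[ids, , drop = FALSE]
  dimnames(X) <- NULL   # token names would ride along every window matrix
  n <- nrow(X)
  k <- ncol(X)
  z <- numeric(0)
  caches <- list()
  for (h in cfg$widths) {
    f <- model$filters[[as.character(h)]]
    nw <- n - h + 1L
    A <- do.call(cbind, lapply(0:(h - 1L), function(o)
      X[(1L + o):(nw + o), , drop = FALSE]))
    if (nw == 1L) A <- matrix(A, nrow = 1L)
    S <- A %*% t(f$W)
    S <- sweep(S, 2L, f$b, "+")
    C <- pmax(S, 0)
    am <- max.col(t(C), ties.method = "first")
    pooled <- C[cbind(am, seq_along(am))]
    caches[[as.character(h)]] <- list(
      am = am,
      active = S[cbind(am, seq_along(am))] > 0,
      rows = A[am, , drop = FALSE])
    z <- c(z, pooled)
  }
  logit <- sum(model$w_out * z) + model$b_out
  list(y = sigmoid(logit), logit = logit, z = z, n = n, n_real = n_real,
       ids = ids, caches = caches)
}

# Gradients of the binary NLL wrt all parameters (and optionally the
# embedded inputs), from a cached forward pass. `mask` is the dropout mask
# on z (NULL = no dropout). Gradients flow only through each filter's
# pooled (argmax) window; ReLU subgradient is 0 at inactive units.
cnn_backward <- function(model, fw, target, mask = NULL, want_dx = FALSE) {
  cfg <- model$config
  m <- cfg$n_filters
  k <- ncol(model$emb)
  z_used <- if (is.null(mask)) fw$z else fw$z * mask
  logit <- sum(model$w_out * z_used) + model$b_out
  y <- sigmoid(logit)
  delta <- y - target
  dz <- delta * model$w_out
  if (!is.null(mask)) dz <- dz * mask
  gW <- list(); gb <- list()
  dX <- if (want_dx) matrix(0, fw$n, k) else NULL
  off <- 0L
  for (h in cfg$widths) {
    ch <- as.character(h)
    cache <- fw$caches[[ch]]
    dzh <- dz[off + seq_len(m)] * as.numeric(cache$active)
    gW[[ch]] <- dzh * cache$rows          # m x (h*k), row-scaled
    gb[[ch]] <- dzh
    if (want_dx) {
      W <- model$filters[[ch]]$W
      for (j in which(dzh != 0)) {
        s <- cache$am[j]
        dX[s:(s + h - 1L), ] <- dX[s:(s + h - 1L), ] +
          dzh[j] * matrix(W[j, ], h, k, byrow = TRUE)
      }
    }
    off <- off + m
  }
  list(gW = gW, gb = gb,
       gw_out = delta * z_used, gb_out = delta,
       dX = dX, y = y, logit = logit,
       loss = nll_from_logit(logit, target))
}

#' Loss of a CNN on one note (no dropout)
#' @param model A `conv_model`.
#' @param ids Encoded note.
#' @param target Label in `{0, 1}`.
#' @return The negative log-likelihood contribution.
#' @export
cnn_loss <- function(model, ids, target) {
  nll_from_logit(cnn_forward(model, ids)$logit, target)
}

new_adam <- function() list(t = 0L, m = list(), v = list())

adam_step <- function(state, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- list()
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) { state$m[[nm]] <- g * 0; state$v[[nm]] <- g * 0 }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    upd[[nm]] <- lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, upd = upd)
}

#' Train a CNN phenotype classifier
#'
#' Mini-batch optimization of the binary negative log-likelihood with
#' dropout on the pooled vector, early stopping on validation F1 (threshold
#' chosen on the validation split by maximizing F1), returning the
#' best-validation checkpoint. Deterministic given the config seed and
#' single-threaded execution.
#'
#' @param train_ids,val_ids Lists of encoded notes.
#' @param train_y,val_y Binary labels (training needs both classes).
#' @param emb Initial embedding matrix (vocab x k).
#' @param vocab The vocabulary.
#' @param config A [cnn_config()].
#' @param verbose Print per-epoch progress?
#' @return A trained `conv_model` with `$threshold` and `$history`.
#' @export
cnn_train <- function(train_ids, train_y, val_ids, val_y, emb, vocab,
                      config = cnn_config(), verbose = FALSE) {
  if (length(unique(train_y)) < 2L)
    stop("training data must contain both classes")
  with_seed(config$seed,
    cnn_train_impl(train_ids, train_y, val_ids, val_y, emb, vocab, config,
                   verbose))
}

cnn_train_impl <- function(train_ids, train_y, val_ids, val_y, emb, vocab,
                           config, verbose) {
  model <- cnn_init(emb, vocab, config)
  n <- length(train_ids)
  m <- config$n_filters
  opt <- new_adam()
  best <- list(f1 = -Inf, model = NULL, epoch = 0L)
  bad_epochs <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_f1 = numeric())

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    total_loss <- 0
    for (bs in seq(1L, n, by = config$batch_size)) {
      idx <- ord[bs:min(bs + config$batch_size - 1L, n)]
      bn <- length(idx)
      acc <- NULL
      dE <- NULL
      touched <- integer(0)
      for (i in idx) {
        fw <- cnn_forward(model, train_ids[[i]])
        mask <- if (config$dropout > 0)
          (runif(length(fw$z)) >= config$dropout) / (1 - config$dropout)
        else NULL
        bw <- cnn_backward(model, fw, train_y[i], mask,
                           want_dx = config$fine_tune)
        if (!is.finite(bw$loss))
          stop("non-finite training loss at epoch ", epoch,
               " (logit = ", bw$logit, ")")
        total_loss <- total_loss + bw$loss
        if (is.null(acc)) {
          acc <- bw[c("gW", "gb", "gw_out", "gb_out")]
        } else {
          for (ch in names(acc$gW)) {
            acc$gW[[ch]] <- acc$gW[[ch]] + bw$gW[[ch]]
            acc$gb[[ch]] <- acc$gb[[ch]] + bw$gb[[ch]]
          }
          acc$gw_out <- acc$gw_out + bw$gw_out
          acc$gb_out <- acc$gb_out + bw$gb_out
        }
        if (config$fine_tune && !is.null(bw$dX)) {
          if (is.null(dE)) dE <- matrix(0, nrow(model$emb), ncol(model$emb))
          nz <- which(rowSums(abs(bw$dX)) > 0)
          if (length(nz) > 0L) {
            # aggregate positions sharing a token id before the row update
            agg <- rowsum(bw$dX[nz, , drop = FALSE], group = fw$ids[nz])
            ridx <- as.integer(rownames(agg))
            dE[ridx, ] <- dE[ridx, ] + agg
            touched <- c(touched, ridx)
          }
        }
      }
      # flatten gradients for the optimizer; L2 on weights, not biases
      grads <- list(w_out = acc$gw_out / bn + config$l2 * model$w_out,
                    b_out = acc$gb_out / bn)
      for (ch in names(acc$gW)) {
        grads[[paste0("W", ch)]] <- acc$gW[[ch]] / bn +
          config$l2 * model$filters[[ch]]$W
        grads[[paste0("b", ch)]] <- acc$gb[[ch]] / bn
      }
      if (config$optimizer == "adam") {
        st <- adam_step(opt, grads, config$lr)
        opt <- st$state
        upd <- st$upd
      } else {
        upd <- lapply(grads, function(g) config$lr * g)
      }
      model$w_out <- model$w_out - upd$w_out
      model$b_out <- model$b_out - upd$b_out
      for (ch in names(acc$gW)) {
        model$filters[[ch]]$W <- model$filters[[ch]]$W - upd[[paste0("W", ch)]]
        model$filters[[ch]]$b <- model$filters[[ch]]$b - upd[[paste0("b", ch)]]
      }
      if (config$fine_tune && length(touched) > 0L) {
        rows <- unique(touched)
        model$emb[rows, ] <- model$emb[rows, ] -
          config$lr_emb * dE[rows, , drop = FALSE] / bn
        model$emb[PAD_INDEX, ] <- 0
      }
    }

    val_scores <- cnn_scores(model, val_ids)
    tt <- if (length(unique(val_y)) > 1L) tune_threshold(val_scores, val_y)
          else list(threshold = 0.5, f1 = 0)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = total_loss / n,
                                   val_f1 = tt$f1))
    if (verbose)
      message(sprintf("epoch %d  train NLL %.4f  val F1 %.3f", epoch,
                      total_loss / n, tt$f1))
    if (tt$f1 > best$f1 + 1e-9) {
      best <- list(f1 = tt$f1, epoch = epoch, threshold = tt$threshold,
                   model = model[c("filters", "w_out", "b_out", "emb")])
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= config$patience) break
    }
  }

  if (!is.null(best$model)) {
    model[c("filters", "w_out", "b_out", "emb")] <- best$model
    model$threshold <- best$threshold
  }
  model$history <- hist
  model$best_epoch <- best$epoch
  model$val_f1 <- best$f1
  model
}

cnn_scores <- function(model, ids_list) {
  vapply(ids_list, function(ids) cnn_forward(model, ids)$y, numeric(1))
}

#' Predict phenotype labels with a trained CNN
#'
#' @param model Trained `conv_model`.
#' @param ids_list List of encoded notes.
#' @param threshold Decision threshold in (0, 1); defaults to the
#'   validation-tuned threshold stored in the model. `label = 1` iff
#'   `y >= threshold`.
#' @return data.frame(score, label).
#' @export
cnn_predict <- function(model, ids_list, threshold = model$threshold) {
  scores <- cnn_scores(model, ids_list)
  data.frame(score = scores, label = as.integer(scores >= threshold))
}

#' Convolution-width ablation
#'
#' Trains one model per width configuration (e.g. `{1}, {1,2}, ..., {1..5}`)
#' over one or more seeds and reports test F1/AUC and the delta against the
#' first (width-1) configuration. The width-`{1}` configuration is exactly
#' the "CNN without convolutions" baseline: several pooled unigram weight
#' vectors combined by a logistic output.
#'
#' @param train_ids,train_y,val_ids,val_y,test_ids,test_y Split data.
#' @param emb,vocab Embeddings and vocabulary.
#' @param widths_list List of width sets; first entry is the reference.
#' @param seeds Integer vector of training seeds.
#' @param base_config A [cnn_config()] supplying all other hyperparameters.
#' @return data.frame(widths, seed, f1, auc, delta_f1).
#' @export
width_ablation <- function(train_ids, train_y, val_ids, val_y,
                           test_ids, test_y, emb, vocab,
                           widths_list = list(1, 1:2, 1:3, 1:4, 1:5),
                           seeds = 1L, base_config = cnn_config()) {
  rows <- list()
  for (seed in seeds) {
    ref_f1 <- NA_real_
    for (wi in seq_along(widths_list)) {
      cfg <- base_config
      cfg$widths <- sort(unique(as.integer(widths_list[[wi]])))
      cfg$seed <- as.integer(seed)
      fit <- cnn_train(train_ids, train_y, val_ids, val_y, emb, vocab, cfg)
      pred <- cnn_predict(fit, test_ids)
      f1 <- f1_score(pred$label, test_y)
      auc <- roc_auc(pred$score, test_y)
      if (wi == 1L) ref_f1 <- f1
      rows[[length(rows) + 1L]] <- data.frame(
        widths = paste(cfg$widths, collapse = ","), seed = seed,
        f1 = f1, auc = auc, delta_f1 = f1 - ref_f1)
    }
  }
  do.call(rbind, rows)
}

#' Save / load a CNN checkpoint
#'
#' A checkpoint directory holds `config.json`, `embeddings.txt` (word2vec
#' text format) and `params.json` (filters, output layer, threshold) —
#' plain text, full double precision, stable filter order.
#'
#' @param model A trained `conv_model`.
#' @param dir Checkpoint directory (created if needed).
#' @export
write_cnn_checkpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(model$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  write_word2vec(model$emb, file.path(dir, "embeddings.txt"))
  params <- list(
    widths = model$config$widths,
    filters = lapply(model$filters, function(f)
      list(W = f$W, b = f$b, h = f$h)),
    w_out = model$w_out, b_out = model$b_out,
    threshold = model$threshold)
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(dir)
}

#' @rdname write_cnn_checkpoint
#' @return `read_cnn_checkpoint` returns a `conv_model`.
#' @export
read_cnn_checkpoint <- function(dir) {
  cfgl <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  config <- cnn_config(widths = cfgl$widths, n_filters = cfgl$n_filters,
                       dropout = cfgl$dropout, l2 = cfgl$l2, lr = cfgl$lr,
                       lr_emb = cfgl$lr_emb, epochs = cfgl$epochs,
                       batch_size = cfgl$batch_size, seed = cfgl$seed,
                       fine_tune = cfgl$fine_tune, patience = cfgl$patience,
                       optimizer = cfgl$optimizer)
  emb <- read_word2vec(file.path(dir, "embeddings.txt"))
  vocab <- structure(list(itos = rownames(emb),
                          counts = rep(NA_integer_, nrow(emb)),
                          min_count = NA_integer_),
                     class = "pheno_vocab")
  params <- jsonlite::read_json(file.path(dir, "params.json"),
                                simplifyVector = TRUE)
  filters <- lapply(params$filters, function(f) {
    W <- f$W
    if (!is.matrix(W)) W <- do.call(rbind, lapply(W, as.numeric))
    if (length(f$b) == 1L && !is.matrix(f$W)) W <- matrix(W, nrow = 1L)
    list(W = W, b = as.numeric(f$b), h = as.integer(f$h))
  })
  structure(list(config = config, emb = emb, vocab = vocab,
                 filters = filters, w_out = as.numeric(params$w_out),
                 b_out = as.numeric(params$b_out),
                 threshold = as.numeric(params$threshold),
                 history = NULL),
            class = "conv_model")
}
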