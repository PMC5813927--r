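#' Benchmark all model families on a corpus
#'
#' The comparison driver: splits the corpus by patient (70/10/20 by
#' default), pre-trains embeddings on all note text (labels unused), then
#' per phenotype trains each requested model family on the training split,
#' tunes its decision threshold on the validation split by maximizing F1,
#' and reports precision/recall/F1/AUC on the test split.
#'
#' Families: `cnn` (multi-width CNN), `bow` (bag-of-words logistic
#' regression), `ngram` (n-gram logistic regression), `concept_full`
#' (TF-IDF bag-of-concepts over the whole dictionary; best of naive Bayes
#' / logistic regression / random forest by validation F1) and
#' `concept_filter` (the same on the phenotype-filtered dictionary,
#' filtering counts before the TF-IDF fit). For the concept families a
#' TF-IDF on/off ablation is recorded. Per-phenotype and pooled
#' chi-squared comparisons of the CNN against both concept arms are
#' included; note this compares per-note correctness counts of two models,
#' one construction among several possible ones (flagged in the report
#' metadata).
#'
#' Degenerate conventions (P/R/F1 set to 0 when undefined) are recorded in
#' the metadata; a phenotype without test positives is flagged and its AUC
#' set to `NA`.
#'
#' @param corpus A `pheno_corpus`.
#' @param models Character vector of model families.
#' @param phenotypes Phenotype names (default: all in the corpus).
#' @param seed Integer seed driving the split and every trainer.
#' @param fractions Split fractions.
#' @param cnn A [cnn_config()].
#' @param ngram_max Maximum n-gram length for the `ngram` family.
#' @param emb Optional pre-trained embedding matrix; trained in-run when
#'   `NULL`.
#' @param emb_k,emb_epochs Embedding dimension / epochs when training here.
#' @param min_count Vocabulary minimum count.
#' @param lr_epochs Epochs for the logistic-regression baselines.
#' @return An object of class `eval_report`: list(metrics, ablation, chi2,
#'   split, meta).
#' @export
benchmark <- function(corpus,
                      models = c("cnn", "bow", "ngram", "concept_full",
                                 "concept_filter"),
                      phenotypes = colnames(corpus$labels),
                      seed = 1L, fractions = c(0.7, 0.1, 0.2),
                      cnn = cnn_config(), ngram_max = 2L,
                      emb = NULL, emb_k = 50L, emb_epochs = 3L,
                      min_count = 2L, lr_epochs = 5000L) {
  seeds <- derive_seeds(seed, 4L)
  split <- grouped_split(corpus$notes, fractions, seed = seeds[1])
  tr <- split$split == "train"; va <- split$split == "val"
  te <- split$split == "test"
  tokens <- corpus$tokens
  vocab <- build_vocab(tokens, min_count = min_count)
  ids <- lapply(tokens, encode_tokens, vocab = vocab)

  need_emb <- "cnn" %in% models
  if (need_emb && is.null(emb))
    emb <- train_embeddings(tokens, vocab, k = emb_k, epochs = emb_epochs,
                            seed = seeds[2])

  need_concepts <- any(c("concept_full", "concept_filter") %in% models)
  if (need_concepts) {
    mentions <- tag_corpus(corpus)
    bags <- build_bags(mentions, corpus$dictionary)
  }
  ng_vocab <- if ("ngram" %in% models)
    ngram_vocab(tokens[tr], 1L, ngram_max) else NULL
  bow_vocab <- if ("bow" %in% models) ngram_vocab(tokens[tr], 1L, 1L) else NULL

  metrics <- list(); ablation <- list(); chi2 <- list()
  test_preds <- list()

  for (p in phenotypes) {
    y <- corpus$labels[, p]
    flag_no_pos <- sum(y[te]) == 0L
    for (fam in models) {
      fit_scores <- switch(fam,
        cnn = {
          cfg <- cnn; cfg$seed <- seeds[3]
          fit <- cnn_train(ids[tr], y[tr], ids[va], y[va], emb, vocab, cfg)
          list(val = cnn_scores(fit, ids[va]), test = cnn_scores(fit, ids[te]))
        },
        bow = lr_family(tokens, y, tr, va, te, bow_vocab, 1L, 1L, lr_epochs),
        ngram = lr_family(tokens, y, tr, va, te, ng_vocab, 1L, ngram_max,
                          lr_epochs),
        concept_full = {
          r <- concept_family(bags, y, tr, va, te, seeds[4])
          ablation[[paste(p, fam)]] <- data.frame(
            phenotype = p, arm = fam, model = r$which,
            auc_tfidf = r$auc_tfidf, auc_counts = r$auc_counts)
          r
        },
        concept_filter = {
          fb <- filter_bags(bags, p, corpus$dictionary)
          r <- concept_family(fb, y, tr, va, te, seeds[4])
          ablation[[paste(p, fam)]] <- data.frame(
            phenotype = p, arm = fam, model = r$which,
            auc_tfidf = r$auc_tfidf, auc_counts = r$auc_counts)
          r
        },
        stop("unknown model family: ", fam))
      tt <- if (length(unique(y[va])) > 1L)
        tune_threshold(fit_scores$val, y[va]) else list(threshold = 0.5)
      pred <- as.integer(fit_scores$test >= tt$threshold)
      cm <- confusion(pred, y[te])
      prf <- prf_metrics(cm["tp"], cm["fp"], cm["tn"], cm["fn"])
      auc <- if (flag_no_pos || length(unique(y[te])) < 2L) NA_real_
             else roc_auc(fit_scores$test, y[te])
      metrics[[paste(p, fam)]] <- data.frame(
        phenotype = p, model = fam,
        precision = prf["precision"], recall = prf["recall"],
        f1 = prf["f1"], auc = auc, threshold = tt$threshold,
        undefined = flag_no_pos, row.names = NULL)
      test_preds[[paste(p, fam)]] <- pred
    }
    for (arm in intersect(c("concept_full", "concept_filter"), models)) {
      if ("cnn" %in% models && !flag_no_pos) {
        cc <- chi2_compare(test_preds[[paste(p, "cnn")]],
                           test_preds[[paste(p, arm)]], y[te])
        chi2[[paste(p, arm)]] <- data.frame(
          phenotype = p, comparison = paste("cnn vs", arm),
          statistic = cc$statistic, p_value = cc$p_value,
          exact_fallback = cc$exact_fallback)
      }
    }
  }

  # pooled chi-squared across phenotypes
  if ("cnn" %in% models) {
    for (arm in intersect(c("concept_full", "concept_filter"), models)) {
      pa <- unlist(lapply(phenotypes, function(p) test_preds[[paste(p, "cnn")]]))
      pb <- unlist(lapply(phenotypes, function(p) test_preds[[paste(p, arm)]]))
      yy <- unlist(lapply(phenotypes, function(p) corpus$labels[te, p]))
      if (!is.null(pa) && !is.null(pb)) {
        cc <- chi2_compare(pa, pb, yy)
        chi2[[paste("pooled", arm)]] <- data.frame(
          phenotype = "(pooled)", comparison = paste("cnn vs", arm),
          statistic = cc$statistic, p_value = cc$p_value,
          exact_fallback = cc$exact_fallback)
      }
    }
  }

  structure(list(
    metrics = do.call(rbind, c(metrics, list(make.row.names = FALSE))),
    ablation = if (length(ablation)) do.call(rbind, ablation) else NULL,
    chi2 = if (length(chi2)) do.call(rbind, chi2) else NULL,
    split = split,
    meta = list(seed = seed, derived_seeds = seeds, fractions = fractions,
                significance_level = 0.01,
                conventions = paste(
                  "P/R/F1 defined as 0 in degenerate cases;",
                  "AUC via Mann-Whitney midranks;",
                  "chi-squared compares per-note correctness of two models",
                  "(one construction among several possible ones)"))),
    class = "eval_report")
}

lr_family <- function(tokens, y, tr, va, te, vocab, n_min, n_max, epochs) {
  xtr <- featurize_ngrams(tokens[tr], vocab, n_min, n_max)
  fit <- train_logistic(xtr, y[tr], epochs = epochs)
  list(val = predict(fit, featurize_ngrams(tokens[va], vocab, n_min, n_max)),
       test = predict(fit, featurize_ngrams(tokens[te], vocab, n_min, n_max)))
}

# Fit NB/LR/RF on TF-IDF concept features (document frequencies estimated
# on the training split only), select by validation F1, and record the
# TF-IDF on/off AUC ablation for the selected model type.
concept_family <- function(bags, y, tr, va, te, seed) {
  N <- sum(tr)
  df <- Matrix::colSums(bags[tr, , drop = FALSE] > 0)
  idf <- ifelse(df > 0, log(N / df), 0)
  W <- bags %*% Matrix::Diagonal(x = idf, n = length(idf))
  colnames(W) <- colnames(bags)
  slice <- function(m, mask) m[mask, , drop = FALSE]
  fits <- list(
    nb = train_naive_bayes(slice(W, tr), y[tr]),
    lr = train_logistic(slice(W, tr), y[tr]),
    rf = train_forest(slice(W, tr), y[tr], seed = seed))
  val_scores <- lapply(fits, function(f) predict(f, slice(W, va)))
  val_f1 <- vapply(val_scores, function(s) {
    if (length(unique(y[va])) < 2L) return(0)
    tune_threshold(s, y[va])$f1
  }, numeric(1))
  which_best <- names(val_f1)[which.max(val_f1)]
  best <- fits[[which_best]]

  auc_or_na <- function(s, yy)
    if (length(unique(yy)) < 2L) NA_real_ else roc_auc(s, yy)
  refit <- switch(which_best,
    nb = train_naive_bayes(slice(bags, tr), y[tr]),
    lr = train_logistic(slice(bags, tr), y[tr]),
    rf = train_forest(slice(bags, tr), y[tr], seed = seed))
  list(val = val_scores[[which_best]],
       test = predict(best, slice(W, te)),
       which = which_best,
       auc_tfidf = auc_or_na(predict(best, slice(W, te)), y[te]),
       auc_counts = auc_or_na(predict(refit, slice(bags, te)), y[te]))
}

#' Write an evaluation report as JSON and TSV
#'
#' @param report An `eval_report` from [benchmark()].
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(metrics = report$metrics, ablation = report$ablation,
         chi2 = report$chi2, meta = report$meta),
    file.path(dir, "report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(report$metrics, file.path(dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$split, file.path(dir, "split_manifest.json"),
                       dataframe = "rows")
  invisible(dir)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> seed", x$meta$seed, "\n")
  m <- x$metrics
  m[, c("precision", "recall", "f1", "auc")] <-
    round(m[, c("precision", "recall", "f1", "auc")], 3)
  print(m[, c("phenotype", "model", "precision", "recall", "f1", "auc")],
        row.names = FALSE)
  invisible(x)
}
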