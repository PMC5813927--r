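test_that("n-gram featurization counts contiguous phrases", {
  toks <- list(d1 = c("the", "sick", "patient"))
  v2 <- ngram_vocab(toks, 2, 2)
  expect_setequal(v2, c("the sick", "sick patient"))
  x2 <- featurize_ngrams(toks, v2, 2, 2)
  expect_true(all(as.matrix(x2) == 1))

  v1 <- ngram_vocab(list(c("a", "a", "b")), 1, 1)
  x1 <- featurize_ngrams(list(c("a", "a", "b")), v1, 1, 1)
  expect_identical(as.numeric(x1[1, "a"]), 2)
  expect_identical(as.numeric(x1[1, "b"]), 1)

  # exactly max(L - n + 1, 0) n-gram instances
  set.seed(4)
  for (n in 1:5) {
    L <- sample(0:8, 1)
    toks <- as.character(sample(letters, L, replace = TRUE))
    expect_identical(length(phenotext:::note_ngrams(toks, n, n)),
                     max(L - n + 1L, 0L))
  }
  expect_error(ngram_vocab(toks, 2, 1), "n_min")
  expect_error(ngram_vocab(toks, 1, 6), "n_min")
})

test_that("bag-of-words is order-invariant; bigrams are not", {
  a <- c("x", "y", "z", "x")
  b <- rev(a)
  v1 <- ngram_vocab(list(a), 1, 1)
  expect_identical(as.matrix(featurize_ngrams(list(a), v1, 1, 1)),
                   as.matrix(featurize_ngrams(list(b), v1, 1, 1)))
  v2 <- ngram_vocab(list(a, b), 2, 2)
  expect_false(identical(as.matrix(featurize_ngrams(list(a), v2, 2, 2)),
                         as.matrix(featurize_ngrams(list(b), v2, 2, 2))))
})

test_that("gradient-descent logistic regression behaves like one", {
  x <- matrix(c(1, -1), 2, 1)
  y <- c(1, 0)
  fit <- train_logistic(x, y, l2 = 1e-4, lr = 0.5, epochs = 300)
  expect_gt(fit$w, 0)
  expect_equal(as.integer(predict(fit, x) >= 0.5), y)
  expect_true(all(diff(fit$loss_history) <= 1e-12))  # descent
  p <- predict(fit, x)
  expect_true(all(p > 0 & p < 1))

  # label flip negates the weight on symmetric data
  flip <- train_logistic(x, 1 - y, l2 = 1e-4, lr = 0.5, epochs = 300)
  expect_equal(flip$w, -fit$w, tolerance = 1e-8)

  # crushing regularization sends weights to zero, predictions to sigma(b)
  crush <- train_logistic(x, y, l2 = 1e6, lr = 1e-6, epochs = 200)
  expect_lt(abs(crush$w), 1e-3)

  expect_error(train_logistic(x, c(1, 1)), "both classes")
})

test_that("multinomial naive Bayes posteriors are calibrated and finite", {
  # disjoint single-feature support: vanishing smoothing gives certainty
  x <- matrix(c(5, 0, 0, 4), 2, 2)
  y <- c(0, 1)
  post <- predict(train_naive_bayes(x, y, alpha = 1e-8), x)
  expect_lt(post[1], 1e-6)
  expect_gt(post[2], 1 - 1e-6)

  # uniform features and priors -> posterior one half
  xu <- matrix(c(2, 2, 2, 2), 2, 2)
  expect_equal(predict(train_naive_bayes(xu, y, alpha = 1), xu),
               c(0.5, 0.5), tolerance = 1e-12)

  set.seed(8)
  xr <- matrix(rpois(60, 2), 10, 6)
  yr <- rep(0:1, 5)
  pr <- predict(train_naive_bayes(xr, yr, alpha = 0.5), xr)
  expect_true(all(is.finite(pr)) && all(pr >= 0 & pr <= 1))

  expect_error(train_naive_bayes(x, y, alpha = 0), "alpha")
  expect_error(train_naive_bayes(-x, y), "non-negative")
})

test_that("random forest gini importance finds a perfect splitter", {
  set.seed(5)
  n <- 120
  x <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  y <- as.integer(x[, 3] > 0)           # label = indicator of feature 3
  fit <- train_forest(x, y, n_trees = 100, seed = 2)
  expect_equal(sum(fit$importance), 1, tolerance = 1e-9)
  rk <- rank_features_gini(fit)
  expect_identical(rk$feature[1], "v3")
  expect_gt(rk$importance[1], 0.5)
  # per-document variant restricts to features present in the document
  expect_identical(rank_features_gini(fit, present = "v2")$feature, "v2")
  # pure-noise features share importance evenly-ish
  imps <- replicate(10, {
    yn <- rbinom(n, 1, 0.5)
    f <- train_forest(x, yn, n_trees = 50, seed = sample.int(1e6, 1))
    max(f$importance) / mean(f$importance)
  })
  expect_lt(max(imps), 3)
  expect_error(train_forest(x[1:3, ], c(1, 1, 0)), "2 samples")
})

test_that("forest predictions are deterministic given the seed", {
  set.seed(6)
  x <- matrix(rnorm(200), 50, 4)
  y <- as.integer(x[, 1] + rnorm(50, 0, 0.4) > 0)
  a <- predict(train_forest(x, y, seed = 9), x)
  b <- predict(train_forest(x, y, seed = 9), x)
  expect_identical(a, b)
})

test_that("pooled-embedding scoring is length-normalized and degenerate-safe", {
  set.seed(7)
  emb <- matrix(rnorm(20), 10, 2); emb[1, ] <- 0
  ids <- list(a = c(3L, 4L, 5L), b = c(6L, 7L, 8L, 9L))
  y <- c(1, 0)
  fit <- train_embed_pool(ids, y, emb, pool = "mean", epochs = 50)
  # duplicating a note leaves its mean-pooled score unchanged
  p1 <- predict(fit, list(ids$a))
  p2 <- predict(fit, list(rep(ids$a, 2)))
  expect_equal(p1, p2, tolerance = 1e-12)
  # all-padding note scores sigma(b)
  expect_equal(predict(fit, list(c(1L, 1L))),
               phenotext:::sigmoid(fit$b), tolerance = 1e-12)
  # max-pool variant trains and predicts in (0,1)
  fm <- train_embed_pool(ids, y, emb, pool = "max", epochs = 30)
  pm <- predict(fm, ids)
  expect_true(all(pm > 0 & pm < 1))
  expect_error(train_embed_pool(ids, c(1, 1), emb), "both classes")
})

test_that("bigram-signal corpora need phrase features: 2-gram LR beats BoW", {
  corp <- bigram_signal_corpus(n_notes = 300, note_length = 120, seed = 31)
  split <- grouped_split(corp$notes, seed = 1)
  tr <- split$split == "train"; te <- split$split == "test"
  y <- corp$labels[, 1]
  f1_for <- function(n_max) {
    v <- ngram_vocab(corp$tokens[tr], 1, n_max)
    fit <- train_logistic(featurize_ngrams(corp$tokens[tr], v, 1, n_max),
                          y[tr], epochs = 150)
    s <- predict(fit, featurize_ngrams(corp$tokens[te], v, 1, n_max))
    f1_score(as.integer(s >= 0.5), y[te])
  }
  expect_gte(f1_for(2) - f1_for(1), 0.05)
})

test_that("linear models round-trip through JSON", {
  x <- matrix(c(1, -1, 2, -2), 4, 1)
  fit <- train_logistic(x, c(1, 0, 1, 0), epochs = 50)
  path <- withr::local_tempfile(fileext = ".json")
  write_linear_model(fit, path)
  back <- read_linear_model(path)
  expect_equal(back$w, fit$w, tolerance = 1e-12)
  expect_equal(predict(back, x), predict(fit, x), tolerance = 1e-12)
})
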