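test_that("phrase saliency equals the sigmoid-NLL closed form exactly", {
  set.seed(30)
  for (r in 1:20) {
    model <- random_small_cnn()
    ids <- random_note(model, 8)
    fw <- cnn_forward(model, ids)
    ps <- phrase_saliency(model, ids)
    closed <- (1 - fw$y) * abs(model$w_out[ps$filter])
    expect_equal(ps$score, closed, tolerance = 1e-12)
    expect_true(all(ps$score >= 0))
  }
})

test_that("phrase saliency matches finite differences on the pooled vector", {
  set.seed(31)
  for (r in 1:5) {
    model <- random_small_cnn()
    ids <- random_note(model, 8)
    fw <- cnn_forward(model, ids)
    ps <- phrase_saliency(model, ids)
    eps <- 1e-6
    for (j in seq_along(fw$z)) {
      sc <- ps$score[ps$filter == j]
      if (length(sc) == 0) {
        expect_identical(fw$z[j], 0)  # only dead maps lack a record
        next
      }
      zp <- fw$z; zp[j] <- zp[j] + eps
      zn <- fw$z; zn[j] <- zn[j] - eps
      fd <- abs(cnn_loss_from_z(model, zp, 1) -
                  cnn_loss_from_z(model, zn, 1)) / (2 * eps)
      expect_equal(sc, fd, tolerance = 1e-4)
    }
  }
})

test_that("dead output weights and saturated positives silence saliency", {
  set.seed(32)
  model <- random_small_cnn(widths = 2, n_filters = 3)
  model$filters[["2"]]$b[] <- 1     # keep every feature map alive
  model$w_out[2] <- 0
  ids <- random_note(model, 6)
  ps <- phrase_saliency(model, ids)
  expect_identical(nrow(ps), 3L)
  expect_identical(ps$score[ps$filter == 2], 0)
  # a confidently positive prediction has (almost) no loss gradient
  model$b_out <- 40
  ps_sat <- phrase_saliency(model, ids)
  expect_lt(max(ps_sat$score), 1e-10)
})

test_that("word saliency is position-wise and zero off the pooled windows", {
  set.seed(33)
  model <- random_small_cnn(widths = 2, n_filters = 2, k = 3)
  ids <- random_note(model, 10)
  fw <- cnn_forward(model, ids)
  ws <- word_saliency(model, ids)
  expect_identical(length(ws), length(ids))
  expect_true(all(ws >= 0))
  covered <- unique(unlist(lapply(fw$caches[["2"]]$am, function(s) s:(s + 1L))))
  expect_true(all(ws[setdiff(seq_along(ids), covered)] == 0))
  # matches the finite-difference norm at a covered position
  i <- covered[1]
  fd <- sqrt(sum(fd_position_grad(model, ids, i)^2))
  expect_equal(ws[i], fd, tolerance = 1e-3)
  # duplicate tokens at different positions may score differently
  ids2 <- c(ids[1:4], ids[1:4], ids[5:6])
  ws2 <- word_saliency(model, ids2)
  expect_identical(length(unique(ws2)), length(unique(round(ws2, 12))))
})

test_that("per-note ranking dedups windows and truncates deterministically", {
  set.seed(34)
  model <- random_small_cnn(widths = 1, n_filters = 4, k = 2)
  # force two filters to pool the same window with different |w_out|
  model$filters[["1"]]$W[2, ] <- model$filters[["1"]]$W[1, ]
  model$filters[["1"]]$b[2] <- model$filters[["1"]]$b[1]
  model$w_out <- c(0.2, 0.9, -0.1, 0.05)
  ids <- random_note(model, 6)
  top <- note_top_phrases(model, ids, top_k = 100)
  expect_lte(max(table(paste(top$start, top$width))), 1L)  # unique windows
  shared <- cnn_forward(model, ids)$caches[["1"]]$am[1]
  kept <- top[top$start == shared & top$width == 1, ]
  expect_identical(kept$filter, 2L)  # larger |w_out| wins the dedup
  expect_true(all(diff(top$score) <= 1e-12))
  expect_identical(nrow(note_top_phrases(model, ids, top_k = 1)), 1L)
  expect_error(note_top_phrases(model, ids, top_k = 0), "top_k")
})

test_that("global ranking reduces to the note ranking and is duplication-stable", {
  set.seed(35)
  model <- random_small_cnn(widths = 1:2, n_filters = 2, k = 2)
  toks <- list(a = sprintf("t%02d", 1:7), b = sprintf("t%02d", c(9, 3, 8, 1, 5)))
  ids <- lapply(toks, encode_tokens, vocab = model$vocab)
  single <- global_top_phrases(model, ids[1], toks[1], top_k = 10)
  note_rank <- note_top_phrases(model, ids[[1]], toks[[1]], top_k = 10)
  dedup <- note_rank[!duplicated(tolower(note_rank$phrase)), ]
  expect_identical(single$phrase, tolower(dedup$phrase))
  expect_equal(single$score, dedup$score, tolerance = 1e-12)
  # duplicating the corpus changes nothing
  doubled <- global_top_phrases(model, c(ids, ids), c(toks, toks), top_k = 10)
  both <- global_top_phrases(model, ids, toks, top_k = 10)
  expect_identical(doubled$phrase, both$phrase)
  expect_equal(doubled$score, both$score, tolerance = 1e-12)
  expect_error(global_top_phrases(model, list(), list()), "empty")
})

test_that("highlighting wraps, merges overlaps and survives empty input", {
  txt <- "heavy etoh abuse with withdrawal"
  expect_identical(highlight_note(txt, NULL), txt)
  one <- data.frame(start = 2, end = 3, score = 0.5)
  out1 <- highlight_note(txt, one)
  expect_identical(out1, "heavy [[etoh abuse|0.5]] with withdrawal")
  two <- data.frame(start = c(2, 3), end = c(3, 4), score = c(0.5, 0.7))
  out2 <- highlight_note(txt, two)
  expect_identical(out2, "heavy [[etoh abuse with|0.7]] withdrawal")
  expect_identical(lengths(regmatches(out2, gregexpr("\\[\\[", out2))), 1L)
})

test_that("saliency artifacts are written as JSON, TSV and HTML", {
  dir <- withr::local_tempdir()
  rec <- data.frame(note_id = "n1", phrase = "etoh abuse", start = 2L,
                    end = 3L, width = 2L, score = 0.5)
  jpath <- file.path(dir, "sal.json")
  write_saliency_json(rec, jpath)
  back <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_identical(back$phrase, "etoh abuse")
  rk <- data.frame(rank = 1L, phrase = "etoh abuse", score = 0.5,
                   note_id = "n1")
  write_ranking_tsv(rk, file.path(dir, "rank.tsv"))
  expect_identical(utils::read.table(file.path(dir, "rank.tsv"),
                                     header = TRUE, sep = "\t")$phrase,
                   "etoh abuse")
  hpath <- file.path(dir, "h.html")
  write_highlight_html(c(n1 = "heavy etoh abuse"),
                       list(n1 = rec), hpath)
  html <- paste(readLines(hpath), collapse = "")
  expect_match(html, "<mark>etoh abuse", fixed = TRUE)
})
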