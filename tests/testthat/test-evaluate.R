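test_that("precision/recall/F1 evaluate exactly, with degenerate conventions", {
  expect_equal(prf_metrics(1, 0, 0, 0), c(precision = 1, recall = 1, f1 = 1))
  expect_equal(prf_metrics(2, 1, 0, 3),
               c(precision = 2 / 3, recall = 2 / 5, f1 = 1 / 2))
  expect_equal(prf_metrics(0, 0, 10, 5), c(precision = 0, recall = 0, f1 = 0))
  cm <- confusion(c(1, 1, 0, 1), c(1, 0, 0, 0))
  expect_identical(unname(cm), c(1L, 2L, 1L, 0L))
})

test_that("rank AUC equals brute-force pair enumeration", {
  expect_identical(roc_auc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_identical(roc_auc(c(0.9, 0.1, 0.8, 0.2), c(1, 1, 0, 0)), 0.5)
  expect_identical(roc_auc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  set.seed(10)
  for (r in 1:25) {
    n <- sample(5:200, 1)
    scores <- round(runif(n), sample(1:3, 1))   # rounding induces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), brute_force_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "undefined")
})

test_that("Cohen's kappa matches hand computation and the null", {
  expect_identical(cohens_kappa(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  # p_o = 0.5, p_e = 0.5 -> kappa 0
  expect_equal(cohens_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  set.seed(12)
  a <- rbinom(5000, 1, 0.4)
  b <- rbinom(5000, 1, 0.6)     # independent annotators
  expect_lt(abs(cohens_kappa(a, b)), 0.05)
  expect_error(cohens_kappa(c(1, 0), c(1, 0, 1)), "length")
})

test_that("2x2 chi-squared matches the closed form and stats::chisq.test", {
  y <- rep(c(1, 0), 75)
  a <- y; a[sample(150, 10)] <- 1 - a[sample(150, 10)]
  # identical predictions -> statistic 0, p 1
  same <- chi2_compare(a, a, y)
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)
  # closed form vs the standard implementation (no continuity correction)
  set.seed(13)
  pa <- rbinom(150, 1, 0.5); pb <- rbinom(150, 1, 0.5)
  cc <- chi2_compare(pa, pb, y)
  ref <- stats::chisq.test(cc$table, correct = FALSE)
  expect_equal(cc$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(cc$p_value, ref$p.value, tolerance = 1e-9)
  # swapping the models leaves the statistic unchanged
  expect_equal(chi2_compare(pb, pa, y)$statistic, cc$statistic)
  # hand-built table: correctness counts 90/10 vs 60/40 -> chi2 = 24
  ya <- rep(1, 150)
  pa2 <- c(rep(1, 90), rep(0, 10), rep(1, 50))
  pb2 <- c(rep(1, 60), rep(0, 40), rep(1, 50))
  cc2 <- chi2_compare(pa2[1:100], pb2[1:100], ya[1:100])
  expect_equal(cc2$statistic, 200 * (90 * 40 - 10 * 60)^2 /
                 (100 * 100 * 150 * 50), tolerance = 1e-9)
  # tiny expected cell -> exact fallback flagged
  expect_warning(out <- chi2_compare(c(1, 1, 0), c(1, 1, 1), c(1, 1, 0)),
                 "expected cell")
  expect_true(out$exact_fallback)
  expect_false(is.na(out$exact_p))
})

test_that("patient-grouped splitting never leaks patients and hits targets", {
  corp <- small_pipeline_corpus(n = 200, seed = 17)
  split <- grouped_split(corp$notes, seed = 3)
  by_pt <- tapply(split$split, split$patient_id,
                  function(s) length(unique(s)))
  expect_true(all(by_pt == 1L))
  expect_identical(grouped_split(corp$notes, seed = 3), split)
  expect_false(identical(grouped_split(corp$notes, seed = 4), split))

  # a 10-note patient lands whole in one split
  notes <- data.frame(note_id = sprintf("n%02d", 1:30),
                      patient_id = c(rep("big", 10), sprintf("p%02d", 1:20)))
  sp <- grouped_split(notes, seed = 1)
  expect_identical(length(unique(sp$split[sp$patient_id == "big"])), 1L)

  expect_error(grouped_split(data.frame(note_id = "a", patient_id = "x")),
               "3 patients")
  expect_error(grouped_split(corp$notes, fractions = c(0.5, 0.2, 0.2)),
               "sum")
})

test_that("threshold tuning is self-consistent on the tuning split", {
  set.seed(14)
  scores <- runif(60)
  labels <- as.integer(scores + rnorm(60, 0, 0.3) > 0.5)
  tt <- tune_threshold(scores, labels)
  expect_identical(f1_score(as.integer(scores >= tt$threshold), labels),
                   tt$f1)
  # no candidate threshold does better
  for (th in c(0, sort(unique(scores)), 1))
    expect_lte(f1_score(as.integer(scores >= th), labels), tt$f1 + 1e-12)
})

test_that("benchmark produces the five-family report shape on a toy corpus", {
  corp <- small_pipeline_corpus(n = 90, prevalence = 0.35, note_length = 60,
                                seed = 23)
  rep <- benchmark(
    corp, models = c("bow", "ngram", "concept_full", "concept_filter"),
    seed = 5, lr_epochs = 80)
  m <- rep$metrics
  expect_setequal(unique(m$model),
                  c("bow", "ngram", "concept_full", "concept_filter"))
  expect_true(all(c("precision", "recall", "f1", "auc") %in% names(m)))
  expect_true(all(m$f1 >= 0 & m$f1 <= 1))
  expect_true(all(is.na(m$auc) | (m$auc >= 0 & m$auc <= 1)))
  # the gold-filtered concept features separate this corpus near-perfectly,
  # and certainly beat the majority-class predictor (F1 = 0)
  expect_gt(m$f1[m$model == "concept_filter"], 0.9)
  expect_identical(nrow(rep$ablation), 2L)
  # identical seeds reproduce the report exactly
  rep2 <- benchmark(
    corp, models = c("bow", "ngram", "concept_full", "concept_filter"),
    seed = 5, lr_epochs = 80)
  expect_identical(rep$metrics, rep2$metrics)
})
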