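#' Patient-grouped train/validation/test split
#'
#' Shuffles patients by seed and greedily assigns each patient's full set of
#' notes to the split with the largest remaining note-count deficit, so all
#' notes of one patient land in one split (no patient leakage) and realized
#' sizes track the 70/10/20 targets up to patient granularity.
#'
#' @param notes data.frame with `note_id` and `patient_id` columns (a
#'   `pheno_corpus$notes` works directly).
#' @param fractions Length-3 numeric summing to 1 (train, validation, test).
#' @param seed Integer seed.
#' @return data.frame(note_id, patient_id, split) with
#'   split in c("train", "val", "test").
#' @export
grouped_split <- function(notes, fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3L)
  patients <- unique(notes$patient_id)
  if (length(patients) < 3L) stop("need at least 3 patients to split")
  notes_per_pt <- table(notes$patient_id)
  target <- fractions * nrow(notes)
  assigned <- c(train = 0, val = 0, test = 0)
  split_of <- character(length(patients))
  names(split_of) <- with_seed(seed, sample(patients))
  for (pt in names(split_of)) {
    deficit <- target - assigned
    pick <- names(deficit)[which.max(deficit)]  # first max: train > val > test
    split_of[pt] <- pick
    assigned[pick] <- assigned[pick] + notes_per_pt[[pt]]
  }
  data.frame(note_id = notes$note_id, patient_id = notes$patient_id,
             split = unname(split_of[notes$patient_id]),
             stringsAsFactors = FALSE)
}

#' Confusion-matrix metrics
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and their harmonic mean F1,
#' evaluated exactly, with the degenerate conventions P = 0 when TP+FP = 0,
#' R = 0 when TP+FN = 0 and F1 = 0 when P+R = 0.
#'
#' @param tp,fp,tn,fn Confusion counts; alternatively pass `pred` and
#'   `truth` binary vectors to [confusion()].
#' @return Named numeric c(precision, recall, f1).
#' @export
prf_metrics <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' @rdname prf_metrics
#' @param pred,truth Binary vectors of predictions and reference labels.
#' @export
confusion <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  c(tp = sum(pred == 1 & truth == 1), fp = sum(pred == 1 & truth == 0),
    tn = sum(pred == 0 & truth == 0), fn = sum(pred == 0 & truth == 1))
}

#' @rdname prf_metrics
#' @export
f1_score <- function(pred, truth) {
  cm <- confusion(pred, truth)
  unname(prf_metrics(cm["tp"], cm["fp"], cm["tn"], cm["fn"])["f1"])
}

#' Rank-based ROC AUC
#'
#' Computed as the Mann--Whitney probability with midrank tie handling:
#' (concordant pairs + 0.5 * tied pairs) / (n_pos * n_neg). Equal in value
#' to trapezoidal ROC integration but exact and directly checkable against
#' brute-force pair enumeration.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary reference labels (needs both classes).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L)
    stop("AUC undefined: need at least one positive and one negative")
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Cohen's kappa for two binary annotators
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement from marginal
#' products; defined as 1 when both observed and expected agreement are 1.
#'
#' @param a,b Equal-length binary label vectors.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a == 1) * mean(b == 1) + mean(a == 0) * mean(b == 0)
  if (abs(1 - pe) < 1e-12) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Chi-squared comparison of two models' correctness
#'
#' Builds the 2x2 table of per-note correctness (model x correct/incorrect)
#' on a shared test set and computes the 1-df chi-squared statistic against
#' independence via the closed form `N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`
#' (no continuity correction). If any expected cell is below 1 a Fisher
#' exact p-value is reported alongside and flagged.
#'
#' @param preds_a,preds_b Binary predictions of the two models.
#' @param labels Shared reference labels.
#' @return list(statistic, p_value, table, exact_fallback, exact_p).
#' @export
chi2_compare <- function(preds_a, preds_b, labels) {
  stopifnot(length(preds_a) == length(labels),
            length(preds_b) == length(labels))
  a <- sum(preds_a == labels); b <- sum(preds_a != labels)
  c_ <- sum(preds_b == labels); d <- sum(preds_b != labels)
  tab <- matrix(c(a, c_, b, d), 2, 2,
                dimnames = list(model = c("A", "B"),
                                outcome = c("correct", "incorrect")))
  N <- sum(tab)
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  stat <- if (denom == 0) 0 else N * (a * d - b * c_)^2 / denom
  expected <- outer(rowSums(tab), colSums(tab)) / N
  fallback <- any(expected < 1)
  exact_p <- if (fallback) fisher.test(tab)$p.value else NA_real_
  if (fallback)
    warning("expected cell below 1; reporting Fisher exact p alongside")
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       table = tab, exact_fallback = fallback, exact_p = exact_p)
}

#' Choose a decision threshold by maximizing F1
#'
#' Scans the midpoints between consecutive distinct scores (plus the
#' extremes) and returns the threshold with the highest F1 on the given
#' labels; ties resolve to the lowest threshold. `label = 1` iff
#' `score >= threshold`.
#'
#' @param scores Validation scores.
#' @param labels Validation labels.
#' @return list(threshold, f1).
#' @export
tune_threshold <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- if (length(s) > 1)
    c(min(s) - 1e-9, (s[-1] + s[-length(s)]) / 2, max(s) + 1e-9)
  else c(s - 1e-9, s + 1e-9)
  f1s <- vapply(cand, function(th) f1_score(as.integer(scores >= th), labels),
                numeric(1))
  best <- which.max(f1s)  # first (lowest) threshold among maximizers
  list(threshold = cand[best], f1 = f1s[best])
}
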