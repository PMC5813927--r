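#' Phenotype specification for the synthetic corpus generator
#'
#' @param name Phenotype name (unique within a config).
#' @param prevalence Probability that a note is positive for this phenotype.
#' @param indicator_phrases List/character vector of indicator phrases
#'   (1--5 tokens each, as whitespace-separated strings).
#' @param synonym_groups Named list mapping an indicator phrase to a character
#'   vector of variants (abbreviations, alternate spellings). If `NULL`,
#'   multi-token phrases automatically receive their initialism as a variant.
#' @return An object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(name, prevalence, indicator_phrases,
                           synonym_groups = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            prevalence >= 0, prevalence < 1)
  indicator_phrases <- as.character(indicator_phrases)
  lens <- lengths(strsplit(indicator_phrases, " ", fixed = TRUE))
  if (any(lens < 1L | lens > 5L))
    stop("indicator phrases must be 1-5 tokens long")
  if (is.null(synonym_groups)) {
    synonym_groups <- list()
    for (p in indicator_phrases) {
      toks <- strsplit(p, " ", fixed = TRUE)[[1]]
      if (length(toks) > 1L)
        synonym_groups[[p]] <- paste(substr(toks, 1L, 1L), collapse = "")
    }
  }
  structure(list(name = name, prevalence = prevalence,
                 indicator_phrases = indicator_phrases,
                 synonym_groups = synonym_groups),
            class = "phenotype_spec")
}

#' Default phenotype set
#'
#' Ten phenotypes whose positive prevalences follow the frequencies of the
#' study corpus the generator emulates (126 to 460 positives out of 1,610
#' notes, i.e. 7.5\%--28.6\%): advanced cancer, advanced heart disease,
#' advanced lung disease, chronic neurologic disease, chronic pain, alcohol
#' abuse, substance abuse, obesity, psychiatric disorders and depression.
#' Each carries a few multi-word indicator phrases with abbreviation or
#' spelling variants.
#'
#' @return A list of [phenotype_spec()] objects.
#' @export
default_phenotypes <- function() {
  list(
    phenotype_spec("advanced_cancer", 161 / 1610,
      c("metastatic cancer", "pancreatic cancer", "stage iv malignancy"),
      list("metastatic cancer" = c("mets", "widely metastatic disease"),
           "pancreatic cancer" = "pancreatic ca",
           "stage iv malignancy" = "stage 4 malignancy")),
    phenotype_spec("advanced_heart_disease", 275 / 1610,
      c("severe cardiomyopathy", "ef 20", "critical aortic stenosis"),
      list("severe cardiomyopathy" = c("ischemic cardiomyopathy", "scm"),
           "ef 20" = c("lvef 20", "ef 15"),
           "critical aortic stenosis" = "severe as")),
    phenotype_spec("advanced_lung_disease", 167 / 1610,
      c("severe copd", "pulmonary fibrosis", "gold stage iv copd"),
      list("severe copd" = "end stage copd",
           "pulmonary fibrosis" = c("ipf", "interstitial lung disease"))),
    phenotype_spec("chronic_neuro", 368 / 1610,
      c("multiple sclerosis", "parkinsons disease", "myasthenia gravis"),
      list("multiple sclerosis" = "ms",
           "parkinsons disease" = "parkinson disease",
           "myasthenia gravis" = "mg")),
    phenotype_spec("chronic_pain", 321 / 1610,
      c("chronic pain", "fibromyalgia", "chronic opioid therapy"),
      list("chronic pain" = "chronic back pain",
           "chronic opioid therapy" = "long term narcotics")),
    phenotype_spec("alcohol_abuse", 196 / 1610,
      c("alcohol abuse", "etoh abuse", "heavy drinking"),
      list("alcohol abuse" = c("alcoholism", "alcohol dependence"),
           "etoh abuse" = "etoh dependence")),
    phenotype_spec("substance_abuse", 155 / 1610,
      c("intravenous drug use", "cocaine abuse", "heroin overdose"),
      list("intravenous drug use" = c("ivdu", "iv drug abuse"),
           "cocaine abuse" = "crack cocaine use")),
    phenotype_spec("obesity", 126 / 1610,
      c("morbid obesity", "bmi 42", "gastric bypass"),
      list("morbid obesity" = c("morbidly obese", "clinical obesity"),
           "bmi 42" = "bmi 38")),
    phenotype_spec("psychiatric_disorders", 295 / 1610,
      c("schizophrenia", "bipolar disorder", "severe anxiety disorder"),
      list("bipolar disorder" = "bipolar affective disorder",
           "severe anxiety disorder" = "generalized anxiety")),
    phenotype_spec("depression", 460 / 1610,
      c("depression", "suicide attempt", "major depressive disorder"),
      list("major depressive disorder" = "mdd",
           "suicide attempt" = "intentional overdose"))
  )
}

#' Configuration for the synthetic corpus generator
#'
#' The generator emulates a de-identified ICU discharge-summary corpus:
#' Zipf-distributed background tokens with light section scaffolding,
#' multiple notes per patient (frequent-flyer structure), per-phenotype
#' binary labels with realistic class imbalance, 1--3 injected non-negated
#' indicator mentions per positive note (with synonym/abbreviation variants
#' and character-level misspellings), and negated decoy mentions in negative
#' notes that must not trigger a positive label.
#'
#' @param n_patients Number of patients.
#' @param notes_per_patient_mean Mean notes per patient; counts are drawn as
#'   1 + geometric, so 1 gives exactly one note per patient.
#' @param phenotypes List of [phenotype_spec()]; defaults to
#'   [default_phenotypes()].
#' @param vocab_size Number of background token types.
#' @param zipf_exponent Zipf exponent for background token frequencies.
#' @param note_length_mean,note_length_sd Background note length in tokens.
#' @param misspelling_rate Per-token probability that an injected mention
#'   token is corrupted (one adjacent swap, drop or duplication).
#' @param variant_rate Probability that an injected mention uses a synonym /
#'   abbreviation variant instead of the canonical phrase.
#' @param negated_decoy_rate Probability that a negative note carries a
#'   negated mention of the phenotype.
#' @param seed Integer seed; equal configs yield byte-identical corpora.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 1000L,
                         notes_per_patient_mean = 1.3,
                         phenotypes = default_phenotypes(),
                         vocab_size = 5000L,
                         zipf_exponent = 1.05,
                         note_length_mean = 600,
                         note_length_sd = 120,
                         misspelling_rate = 0.05,
                         variant_rate = 0.3,
                         negated_decoy_rate = 0.3,
                         seed = 1L) {
  probs <- c(misspelling_rate, variant_rate, negated_decoy_rate,
             vapply(phenotypes, function(p) p$prevalence, numeric(1)))
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (n_patients < 1L) stop("n_patients must be >= 1")
  nm <- vapply(phenotypes, function(p) p$name, character(1))
  if (anyDuplicated(nm)) stop("phenotype names must be unique")
  indicator_tokens <- unique(unlist(lapply(phenotypes, function(p)
    tokenize(paste(c(p$indicator_phrases, unlist(p$synonym_groups)), collapse = " ")))))
  if (vocab_size < length(indicator_tokens))
    stop("vocab_size (", vocab_size, ") too small to host the ",
         length(indicator_tokens), " distinct indicator-phrase tokens")
  structure(list(n_patients = as.integer(n_patients),
                 notes_per_patient_mean = notes_per_patient_mean,
                 phenotypes = phenotypes, vocab_size = as.integer(vocab_size),
                 zipf_exponent = zipf_exponent,
                 note_length_mean = note_length_mean,
                 note_length_sd = note_length_sd,
                 misspelling_rate = misspelling_rate,
                 variant_rate = variant_rate,
                 negated_decoy_rate = negated_decoy_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Apply one character-level corruption to a token
#'
#' Applies exactly one of: swap two adjacent characters, drop a character,
#' or duplicate a character. Single-character tokens can only be duplicated.
#' The result is non-empty and within Levenshtein distance 2 of the input.
#' Uses the current RNG state.
#'
#' @param token Non-empty character scalar.
#' @return The corrupted token.
#' @export
corrupt_token <- function(token) {
  stopifnot(is.character(token), length(token) == 1L, nchar(token) >= 1L)
  ch <- strsplit(token, "", fixed = TRUE)[[1]]
  n <- length(ch)
  op <- if (n == 1L) "dup" else sample(c("swap", "drop", "dup"), 1L)
  out <- switch(op,
    swap = { i <- sample.int(n - 1L, 1L); ch[c(i, i + 1L)] <- ch[c(i + 1L, i)]; ch },
    drop = ch[-sample.int(n, 1L)],
    dup  = { i <- sample.int(n, 1L); append(ch, ch[i], after = i) })
  paste(out, collapse = "")
}

# Negation triggers injected before decoy mentions (single surface forms
# chosen so the NegEx-style detector and a width>=3 convolution can both
# see them).
DECOY_TRIGGERS <- list("denies", "no", "without", c("negative", "for"), "not")

SECTION_HEADERS <- list(
  c("history", "of", "present", "illness"),
  c("past", "medical", "history"),
  c("discharge", "diagnosis"))

zipf_probs <- function(v, s) { p <- (1:v)^(-s); p / sum(p) }

draw_zipf <- function(n, cum_p) findInterval(runif(n), cum_p) + 1L

#' Generate a synthetic annotated note corpus
#'
#' See [synth_config()] for the generative model. Alongside the notes the
#' corpus carries gold mention spans (so saliency and tagging output can be
#' scored against ground truth) and a gold concept dictionary (one concept
#' per indicator phrase group, tagged with its phenotype).
#'
#' Label consistency holds by construction: a note is labeled 1 for a
#' phenotype iff it contains at least one non-negated injected mention of
#' it; negative notes receive at most a negated decoy mention.
#'
#' @param config A [synth_config()].
#' @return An object of class `pheno_corpus`: list with `notes` (data.frame
#'   note_id, patient_id, text), `tokens` (named list of token vectors),
#'   `labels` (binary matrix notes x phenotypes), `gold_spans` (data.frame
#'   note_id, phenotype, start, end, negated; 1-based inclusive token
#'   positions), `dictionary` (a [concept_dictionary()]) and `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  phen_names <- vapply(config$phenotypes, function(p) p$name, character(1))
  bg_vocab <- sprintf("w%04d", seq_len(config$vocab_size))
  cum_p <- cumsum(zipf_probs(config$vocab_size, config$zipf_exponent))

  # notes per patient
  extra <- if (config$notes_per_patient_mean > 1)
    rgeom(config$n_patients, 1 / config$notes_per_patient_mean) else
    integer(config$n_patients)
  n_notes_per_pt <- 1L + extra
  n_notes <- sum(n_notes_per_pt)
  patient_id <- rep(sprintf("pt%05d", seq_len(config$n_patients)), n_notes_per_pt)
  note_id <- sprintf("note%06d", seq_len(n_notes))

  labels <- matrix(0L, n_notes, length(phen_names),
                   dimnames = list(note_id, phen_names))
  for (j in seq_along(phen_names))
    labels[, j] <- rbinom(n_notes, 1L, config$phenotypes[[j]]$prevalence)

  tokens <- vector("list", n_notes)
  names(tokens) <- note_id
  spans <- vector("list", n_notes)

  for (i in seq_len(n_notes)) {
    len <- max(30L, as.integer(round(rnorm(1, config$note_length_mean,
                                           config$note_length_sd))))
    bg <- bg_vocab[draw_zipf(len, cum_p)]
    # light section scaffolding: most (not all) notes carry each header, at
    # note-specific positions, as in real dictated summaries
    for (hd in SECTION_HEADERS) {
      if (runif(1) < 0.8)
        bg <- append(bg, hd, after = sample.int(length(bg) + 1L, 1L) - 1L)
    }

    # plan insertions: list of token vectors + which slice is the mention
    ins <- list()
    for (j in seq_along(phen_names)) {
      spec <- config$phenotypes[[j]]
      if (labels[i, j] == 1L) {
        for (r in seq_len(sample(3L, 1L))) {
          ins[[length(ins) + 1L]] <- list(
            tokens = render_mention(spec, config), phenotype = phen_names[j],
            negated = FALSE, trigger_len = 0L)
        }
      } else if (runif(1) < config$negated_decoy_rate) {
        trig <- DECOY_TRIGGERS[[sample.int(length(DECOY_TRIGGERS), 1L)]]
        ins[[length(ins) + 1L]] <- list(
          tokens = c(trig, render_mention(spec, config)),
          phenotype = phen_names[j], negated = TRUE,
          trigger_len = length(trig))
      }
    }

    if (length(ins) == 0L) {
      tokens[[i]] <- bg
      next
    }
    pos <- sort(sample.int(length(bg) + 1L, length(ins), replace = TRUE))
    out <- character(0)
    sp <- vector("list", length(ins))
    cursor <- 1L
    for (s in seq_along(ins)) {
      if (pos[s] > cursor) out <- c(out, bg[cursor:(pos[s] - 1L)])
      piece <- ins[[s]]
      start <- length(out) + 1L + piece$trigger_len
      out <- c(out, piece$tokens)
      sp[[s]] <- data.frame(note_id = note_id[i], phenotype = piece$phenotype,
                            start = start,
                            end = start + length(piece$tokens) - piece$trigger_len - 1L,
                            negated = piece$negated, stringsAsFactors = FALSE)
      cursor <- pos[s]
    }
    if (cursor <= length(bg)) out <- c(out, bg[cursor:length(bg)])
    tokens[[i]] <- out
    spans[[i]] <- do.call(rbind, sp)
  }

  gold_spans <- do.call(rbind, spans[!vapply(spans, is.null, logical(1))])
  if (is.null(gold_spans))
    gold_spans <- data.frame(note_id = character(), phenotype = character(),
                             start = integer(), end = integer(),
                             negated = logical(), stringsAsFactors = FALSE)
  rownames(gold_spans) <- NULL

  notes <- data.frame(note_id = note_id, patient_id = patient_id,
                      text = vapply(tokens, paste, character(1), collapse = " "),
                      stringsAsFactors = FALSE, row.names = NULL)

  structure(list(notes = notes, tokens = tokens, labels = labels,
                 gold_spans = gold_spans,
                 dictionary = gold_dictionary(config$phenotypes),
                 config = config),
            class = "pheno_corpus")
}

# Draw one surface realisation of an indicator mention: canonical phrase or
# variant, then per-token misspelling.
render_mention <- function(spec, config) {
  phrase <- spec$indicator_phrases[sample.int(length(spec$indicator_phrases), 1L)]
  variants <- spec$synonym_groups[[phrase]]
  if (!is.null(variants) && length(variants) > 0L && runif(1) < config$variant_rate)
    phrase <- variants[sample.int(length(variants), 1L)]
  toks <- strsplit(phrase, " ", fixed = TRUE)[[1]]
  miss <- runif(length(toks)) < config$misspelling_rate
  toks[miss] <- vapply(toks[miss], corrupt_token, character(1))
  toks
}

#' @export
print.pheno_corpus <- function(x, ...) {
  cat("<pheno_corpus> ", nrow(x$notes), " notes, ",
      length(unique(x$notes$patient_id)), " patients, ",
      ncol(x$labels), " phenotypes\n", sep = "")
  prev <- round(colMeans(x$labels), 3)
  cat("positive fraction: ", paste(names(prev), prev, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Simulate a second annotator
#'
#' Flips each binary label independently with probability
#' `disagreement_rate`, producing a label table of the same shape. Used to
#' exercise inter-rater agreement (Cohen's kappa) downstream.
#'
#' @param labels Binary matrix or vector.
#' @param disagreement_rate Flip probability in \[0, 1\].
#' @param seed Integer seed.
#' @return Labels of the same shape with flips applied.
#' @export
second_annotator <- function(labels, disagreement_rate, seed = 1L) {
  if (disagreement_rate < 0 || disagreement_rate > 1)
    stop("disagreement_rate must be in [0, 1]")
  stopifnot(all(labels %in% c(0L, 1L)))
  with_seed(seed, {
    flip <- runif(length(labels)) < disagreement_rate
    out <- labels
    out[flip] <- 1L - out[flip]
    out
  })
}

# ---- planted-signal corpora for ablation studies ------------------------

#' Corpora with controlled phrase-length signal
#'
#' `bigram_signal_corpus()` plants a label carried *only* by the adjacency
#' of a two-token phrase: positive notes contain the bigram "alpha beta";
#' negative notes contain both unigrams "alpha" and "beta" at separated
#' positions. Unigram feature counts are therefore uninformative and only
#' width-2 (or wider) features can separate the classes.
#' `unigram_signal_corpus()` plants a single-token indicator, so features
#' wider than one word cannot help.
#'
#' @param n_notes Number of notes (one per patient).
#' @param prevalence Positive fraction.
#' @param note_length Mean background length in tokens.
#' @param seed Integer seed.
#' @return A `pheno_corpus` with one phenotype `signal`.
#' @export
bigram_signal_corpus <- function(n_notes = 400L, prevalence = 0.5,
                                 note_length = 200, seed = 1L) {
  cfg <- synth_config(
    n_patients = n_notes, notes_per_patient_mean = 1,
    phenotypes = list(phenotype_spec("signal", prevalence, "alpha beta",
                                     synonym_groups = list())),
    vocab_size = 1000L, note_length_mean = note_length,
    note_length_sd = note_length / 10,
    misspelling_rate = 0, variant_rate = 0, negated_decoy_rate = 0,
    seed = seed)
  corp <- generate_corpus(cfg)
  # plant the unigrams (non-adjacent) into every negative note
  with_seed(derive_seeds(seed, 2L)[2], {
    for (i in which(corp$labels[, "signal"] == 0L)) {
      tk <- corp$tokens[[i]]
      p <- sort(sample.int(length(tk) - 6L, 2L))
      tk <- append(tk, "alpha", after = p[1])
      tk <- append(tk, "beta", after = p[2] + 2L)  # always >= 1 token apart
      corp$tokens[[i]] <- tk
      corp$notes$text[i] <- paste(tk, collapse = " ")
    }
  })
  # token positions shifted for negatives only; gold spans (positives) are
  # unaffected by the negative-note edits
  corp
}

#' @rdname bigram_signal_corpus
#' @export
unigram_signal_corpus <- function(n_notes = 400L, prevalence = 0.5,
                                  note_length = 200, seed = 1L) {
  cfg <- synth_config(
    n_patients = n_notes, notes_per_patient_mean = 1,
    phenotypes = list(phenotype_spec("signal", prevalence, "zeta",
                                     synonym_groups = list())),
    vocab_size = 1000L, note_length_mean = note_length,
    note_length_sd = note_length / 10,
    misspelling_rate = 0, variant_rate = 0, negated_decoy_rate = 0,
    seed = seed)
  generate_corpus(cfg)
}
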