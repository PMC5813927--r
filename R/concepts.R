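#' Concept dictionary
#'
#' Maps concept identifiers (CUI-like ids) to surface token sequences and
#' phenotype tags — the stand-in for a clinician-specified concept
#' dictionary backing a clinical entity extractor.
#'
#' @param concept_id Character vector, one entry per (concept, surface) pair.
#' @param phrase Surface phrases (whitespace-separated tokens), parallel to
#'   `concept_id`.
#' @param phenotype Phenotype tag per pair (used by the filtered arm).
#' @param display Optional display name per concept.
#' @return Object of class `concept_dictionary`: data.frame with columns
#'   concept_id, phrase, phenotype, display; surfaces are stored pre-tokenized
#'   in the `tokens` list column.
#' @export
concept_dictionary <- function(concept_id, phrase, phenotype,
                               display = NULL) {
  stopifnot(length(concept_id) == length(phrase),
            length(phrase) == length(phenotype))
  toks <- lapply(phrase, tokenize)
  if (any(lengths(toks) == 0L)) stop("surface forms must be non-empty")
  norm <- vapply(toks, paste, character(1), collapse = " ")
  if (anyDuplicated(paste(concept_id, norm)))
    stop("duplicate (concept, surface) pair")
  d <- data.frame(concept_id = as.character(concept_id), phrase = norm,
                  phenotype = as.character(phenotype),
                  display = if (is.null(display)) norm else as.character(display),
                  stringsAsFactors = FALSE)
  d$tokens <- toks
  class(d) <- c("concept_dictionary", "data.frame")
  d
}

# Gold dictionary for a synthetic phenotype set: one concept per indicator
# phrase; its variants are additional surfaces of the same concept.
# Misspelled realisations are deliberately absent.
gold_dictionary <- function(phenotypes) {
  rows <- list()
  cid <- 0L
  for (spec in phenotypes) {
    for (phrase in spec$indicator_phrases) {
      cid <- cid + 1L
      surfaces <- c(phrase, spec$synonym_groups[[phrase]])
      for (s in surfaces)
        rows[[length(rows) + 1L]] <- data.frame(
          concept_id = sprintf("C%04d", cid), phrase = s,
          phenotype = spec$name, display = phrase, stringsAsFactors = FALSE)
    }
  }
  r <- do.call(rbind, rows)
  concept_dictionary(r$concept_id, r$phrase, r$phenotype, r$display)
}

#' Read/write a concept dictionary as TSV
#'
#' Columns: concept_id, phrase, phenotype (tab-separated, no header quoting).
#' @param dictionary A [concept_dictionary()].
#' @param path File path.
#' @return `read_dictionary_tsv` returns a [concept_dictionary()].
#' @export
write_dictionary_tsv <- function(dictionary, path) {
  utils::write.table(dictionary[, c("concept_id", "phrase", "phenotype")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dictionary_tsv
#' @export
read_dictionary_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "")
  concept_dictionary(d$concept_id, d$phrase, d$phenotype)
}

#' Tag concept mentions in a tokenized note
#'
#' Greedy left-to-right longest-match dictionary tagging: at each position
#' the longest matching surface is consumed (ties between equally long
#' surfaces broken by lexicographic concept id), so spans never overlap.
#'
#' @param tokens Character vector of note tokens.
#' @param dictionary A [concept_dictionary()].
#' @return data.frame(concept_id, start, end, negated) with 1-based
#'   inclusive token spans; `negated` is `NA` until [detect_negation()] /
#'   [tag_corpus()] fills it.
#' @export
tag_concepts <- function(tokens, dictionary) {
  empty <- data.frame(concept_id = character(), start = integer(),
                      end = integer(), negated = logical(),
                      stringsAsFactors = FALSE)
  if (length(tokens) == 0L || nrow(dictionary) == 0L) return(empty)
  ord <- order(-lengths(dictionary$tokens), dictionary$concept_id,
               method = "radix")
  surf <- dictionary$tokens[ord]
  cids <- dictionary$concept_id[ord]
  first <- vapply(surf, `[`, character(1), 1L)
  by_first <- split(seq_along(surf), first)

  res <- list()
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    cand <- by_first[[tokens[i]]]
    matched <- FALSE
    if (!is.null(cand)) {
      for (s in cand) {  # candidates already longest-first
        L <- length(surf[[s]])
        if (i + L - 1L <= n && all(tokens[i:(i + L - 1L)] == surf[[s]])) {
          res[[length(res) + 1L]] <- list(cid = cids[s], start = i,
                                          end = i + L - 1L)
          i <- i + L
          matched <- TRUE
          break
        }
      }
    }
    if (!matched) i <- i + 1L
  }
  if (length(res) == 0L) return(empty)
  data.frame(concept_id = vapply(res, `[[`, character(1), "cid"),
             start = vapply(res, `[[`, integer(1), "start"),
             end = vapply(res, `[[`, integer(1), "end"),
             negated = NA, stringsAsFactors = FALSE)
}

NEGATION_TRIGGERS <- list("no", "denies", "denied", "without", "not",
                          c("negative", "for"), c("free", "of"))
NEGATION_TERMINATORS <- c("but", "however")

#' NegEx-style negation detection for a concept mention
#'
#' A mention is negated iff a pre-trigger ("no", "denies", "without",
#' "negative for", "not", ...) ends within `scope_window` tokens before the
#' mention start and no termination token ("but", "however") occurs between
#' the trigger and the mention.
#'
#' @param tokens Note tokens.
#' @param start 1-based token index of the mention start.
#' @param scope_window Look-back window in tokens (default 5).
#' @param triggers List of trigger token sequences.
#' @param terminators Character vector of scope terminators.
#' @return Logical scalar.
#' @export
detect_negation <- function(tokens, start, scope_window = 5L,
                            triggers = NEGATION_TRIGGERS,
                            terminators = NEGATION_TERMINATORS) {
  for (d in seq_len(min(scope_window, start - 1L))) {
    p <- start - d           # trigger would end at position p
    if (tokens[p] %in% terminators) return(FALSE)
    for (tr in triggers) {
      L <- length(tr)
      if (p - L + 1L >= 1L && all(tokens[(p - L + 1L):p] == tr)) return(TRUE)
    }
  }
  FALSE
}

#' Tag a whole corpus and resolve negation flags
#'
#' @param corpus A `pheno_corpus` (or a named list of token vectors).
#' @param dictionary A [concept_dictionary()]; defaults to the corpus gold
#'   dictionary.
#' @param scope_window Negation look-back window.
#' @return Named list of per-note mention data.frames (see [tag_concepts()]),
#'   with `negated` filled in.
#' @export
tag_corpus <- function(corpus, dictionary = NULL, scope_window = 5L) {
  tokens_list <- if (inherits(corpus, "pheno_corpus")) corpus$tokens else corpus
  if (is.null(dictionary)) dictionary <- corpus$dictionary
  lapply(tokens_list, function(tk) {
    m <- tag_concepts(tk, dictionary)
    if (nrow(m) > 0L)
      m$negated <- vapply(m$start, function(s)
        detect_negation(tk, s, scope_window), logical(1))
    m
  })
}

#' Bag-of-concepts counts with negation separation
#'
#' Counts mentions per note keyed by (concept, negated flag) — negated and
#' non-negated occurrences of a concept are distinct features. Returns a
#' sparse count matrix whose columns are named `<concept_id>|aff` and
#' `<concept_id>|neg`.
#'
#' @param mentions Named list of mention data.frames from [tag_corpus()].
#' @param dictionary The [concept_dictionary()] defining the feature space.
#' @param separate_negation If `FALSE`, negated and affirmed counts are
#'   merged into one feature per concept (ablation of the separation).
#' @return A `dgCMatrix` (notes x features).
#' @export
build_bags <- function(mentions, dictionary, separate_negation = TRUE) {
  concepts <- sort(unique(dictionary$concept_id))
  feats <- if (separate_negation)
    c(paste0(concepts, "|aff"), paste0(concepts, "|neg")) else concepts
  n <- length(mentions)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_len(n)) {
    m <- mentions[[i]]
    if (nrow(m) == 0L) next
    key <- if (separate_negation)
      paste0(m$concept_id, ifelse(m$negated, "|neg", "|aff")) else m$concept_id
    tab <- table(key)
    ii <- c(ii, rep.int(i, length(tab)))
    jj <- c(jj, match(names(tab), feats))
    xx <- c(xx, as.numeric(tab))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, length(feats)),
                       dimnames = list(names(mentions), feats))
}

#' TF-IDF weighting of a count matrix
#'
#' `weight(d, t) = count(d, t) * ln(N / df(t))` with `df(t)` the number of
#' documents in which feature `t` occurs. Unsmoothed: a feature present in
#' every document gets weight 0 everywhere.
#'
#' @param counts Sparse or dense count matrix (documents x features).
#' @return Matrix of the same shape with TF-IDF weights.
#' @export
tfidf_transform <- function(counts) {
  N <- nrow(counts)
  if (N == 0L) stop("TF-IDF undefined for an empty document set")
  df <- Matrix::colSums(counts > 0)
  idf <- ifelse(df > 0, log(N / df), 0)
  counts %*% Matrix::Diagonal(x = idf, n = length(idf))
}

#' Restrict bag features to one phenotype's tagged concepts
#'
#' The clinician-filtered arm: keeps only features whose concept carries the
#' phenotype tag in the dictionary; counts are unchanged.
#'
#' @param bags Count (or TF-IDF) matrix from [build_bags()].
#' @param phenotype Phenotype name.
#' @param dictionary The tagged [concept_dictionary()].
#' @return The column-subset matrix.
#' @export
filter_bags <- function(bags, phenotype, dictionary) {
  if (!phenotype %in% dictionary$phenotype)
    stop("unknown phenotype: ", phenotype)
  keep_cid <- unique(dictionary$concept_id[dictionary$phenotype == phenotype])
  base <- sub("\\|(aff|neg)$", "", colnames(bags))
  bags[, base %in% keep_cid, drop = FALSE]
}

#' Export a bag matrix as sparse triplet text or MatrixMarket
#'
#' @param bags Sparse matrix from [build_bags()].
#' @param path Output path; `.mtx` writes MatrixMarket (via
#'   [Matrix::writeMM()]), anything else writes a `note_id feature value`
#'   TSV of nonzero entries.
#' @export
write_bags <- function(bags, path) {
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(methods::as(bags, "CsparseMatrix"), path)
  } else {
    t3 <- Matrix::summary(methods::as(bags, "CsparseMatrix"))
    out <- data.frame(note_id = rownames(bags)[t3$i],
                      feature = colnames(bags)[t3$j], value = t3$x)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
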