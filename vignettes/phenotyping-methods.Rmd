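---
title: "Phrase-based phenotyping of clinical notes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phrase-based phenotyping of clinical notes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phenotext` infers binary patient phenotypes — conditions such as alcohol
abuse, obesity or advanced heart disease — from free-text clinical
narratives, and explains its predictions by pointing at the phrases that
drove them. This vignette describes the models the package implements,
the assumptions behind them, the knobs that matter, and what the synthetic
benchmark corpus does and does not demonstrate.

## The classification model

Each note is tokenized (lowercase, split on non-alphanumeric runs, numbers
kept — ejection fractions and BMI values carry signal) and embedded: token
$i$ becomes a vector $x_i \in \mathbb{R}^k$ from a table pre-trained with
skip-gram negative sampling on all available note text. A convolution
filter of width $h$ with weights $w \in \mathbb{R}^{hk}$ and bias $b$
produces a feature map over all token windows,

$$c_i = \mathrm{ReLU}(w \cdot x_{i:i+h-1} + b), \qquad
  \hat{c} = \max_i c_i,$$

and max-over-time pooling keeps each map's single most predictive value.
The package trains banks of filters for widths 1 through 5 — clinical
evidence is phrasal ("severe aortic stenosis", "EF 20 30"), rarely longer
than five words. The pooled values are concatenated into $z$ and the
prediction is $y = \sigma(w_{\text{out}} \cdot z + b_{\text{out}})$. One
model is trained per phenotype by minimizing the binary negative
log-likelihood, with dropout on $z$, mini-batch Adam updates, and early
stopping on validation F1. The width-$\{1\}$ configuration is exactly the
"several pooled unigram scorers + logistic output" baseline, which makes
width ablations interpretable.

Numerical choices: the loss is evaluated through a log1p-based softplus so
long notes with large logits cannot overflow; max-pooling ties break to
the lowest window index so saliency attribution is deterministic; notes
shorter than the largest width are right-padded with a zero embedding row
that is never updated; gradients flow only through each filter's argmax
window (ReLU subgradient 0 at inactive units). Filter and output weights
take Adam steps; fine-tuned embedding rows take plain SGD steps on the
(few) rows inside pooled windows — dense Adam moments over the whole
embedding table would cost memory and time for no measurable benefit at
this scale. A small weight decay (`l2`, default 5e-4) is applied to filter
and output weights only; its role is to discourage filters that track
features constant across notes, which are redundant with the output bias.

Defaults are 32 filters per width and $k = 50$ embedding dimensions.
Desk-scale synthetic corpora with a 5,000-type vocabulary do not need more
capacity, and planted-signal recovery is unchanged against 100/100; both
are config fields for larger corpora.

## Saliency interpretation

For a trained model and a note, word saliency scores position $i$ by the
norm of the loss gradient with respect to that position's embedding
vector, $S(x_i) = \lVert \partial L(1, y)/\partial x_i \rVert_2$, with the
loss evaluated against target label 1. Phrase saliency extends this to
feature maps: filter $j$'s score is
$\lvert \partial L(1, y)/\partial \hat{c}_j \rvert$, attributed to the
token window the filter pooled. For this architecture the chain rule gives
the closed form $(1 - y)\,\lvert w_{\text{out},j} \rvert$, which the test
suite holds the implementation to (and cross-checks against central finite
differences; near exact pooling ties the one-sided derivative makes finite
differences disagree by construction, so oracle fixtures use notes with
distinct tokens).

Attribution needs an argmax window to point at, so two degenerate cases
are excluded from phrase records: windows lying entirely in right-padding,
and filters whose feature map is identically zero after the ReLU — a dead
map's "argmax" is an arbitrary tie at the first window, and reporting it
would decorate meaningless note-start windows with real gradient mass.
Per note, the best-scoring record per distinct window is kept, sorted, and
truncated. The corpus-level ranking pools per-note records, collapses
duplicate phrases (lowercased, whitespace-collapsed) keeping the maximum
score, and truncates. One consequence of the closed form deserves
emphasis: the factor $(1 - y)$ makes confidently *negative* notes the
highest-saliency documents toward target 1, and their argmax windows are
arbitrary background text. Ranking phrases *for* a phenotype is therefore
meaningful on notes that exhibit it, and the pipeline default feeds the
predicted-positive subset to the global ranking; `global_top_phrases()`
itself ranks whatever notes it is given. A further consequence is that the
ranking favors *borderline* positives — which is informative: on the
synthetic benchmark the top global phrases are typically misspelled
mention variants and negated decoy windows, i.e. exactly the hard
evidence.

## Concept-extraction baseline

The concept arm stands in for a clinical entity extractor: a dictionary
tagger (greedy left-to-right longest match over tokenized surfaces) plus
NegEx-style negation — a mention is negated iff a trigger ("no", "denies",
"without", "negative for", "not", ...) ends within 5 tokens before it with
no intervening "but"/"however". Negated and affirmed mentions are counted
as *separate* features per concept; merging them measurably hurts, because
negative notes can mention a condition in negated form. Counts are TF-IDF
weighted as $\text{count} \times \ln(N/\text{df})$ — unsmoothed and
unnormalized, so a feature present in every document is exactly zero and
small cases can be verified by hand. Document frequencies are estimated on
the training split only. The clinician-filtered arm restricts counts to
the phenotype's tagged concepts *before* the TF-IDF fit (the alternative
order — weight first, filter after — changes df estimates of retained
features; we fix one order and flag it rather than guess). Naive Bayes
(multinomial, Laplace-smoothed), logistic regression and a random forest
(`ranger`, gini importance, seeded, single-threaded) are fit on these
features and the benchmark selects per phenotype by validation F1. The
logistic trainer is deliberately plain full-batch gradient descent so its
descent and symmetry properties are assertable; its default step is the
guaranteed-descent bound `1/L`, `L = mean ||x_i||^2/4 + l2`, computed from
the data before iterating (raw count features put heavy mass on frequent
background tokens, where an aggressive fixed step diverges), with enough
epochs that each fit is a few seconds of sparse matrix-vector products. Word-sense disambiguation, UMLS
lookup and spelling normalization are out of scope: the tagger is a
feature-extraction stand-in, not an entity-extractor clone.

## Synthetic corpus generator

Real annotated discharge summaries are access-restricted, so the package
ships a generator that emulates the *statistical structure* such a corpus
exposes to these models: Zipf-distributed background tokens (exponent
1.05, 5,000 types); mean note length 600 tokens; light section scaffolding
("history of present illness", "discharge diagnosis"), each header present
in ~80% of notes at note-specific positions — headers in *every* note at a
fixed position would create a constant pooled feature no real corpus has;
multiple notes per patient (1 + geometric, mean 1.3, emulating repeat ICU
patients and making patient-grouped splitting consequential); ten default
phenotypes with prevalences between 7.5% and 28.6%; 1–3 injected
non-negated indicator mentions per positive note, with synonym /
abbreviation variants (multi-token phrases also get their initialism) and
character-level misspellings (one adjacent swap, drop or duplication per
corrupted token); and negated decoy mentions in 30% of negative notes (the
rate real negatives mention a condition in negated or historical form is
not documented; 0.3 is a fixed package choice). Labels are consistent by
construction — positive iff a non-negated mention is present — and every
mention's token span is recorded as gold, so tagging and saliency can be
scored exactly.

What passing tests on this corpus do **not** show: robustness to real
clinical language (template boilerplate, de-identification artifacts,
section-dependent semantics, label noise), to indicator phrases that are
also common benign n-grams, or to concepts expressed only by
paraphrase. The generator's signal is planted and hence recoverable; the
tests establish that the implementations are correct and that the
*relative* claims (width ablation direction, pooled-embedding degeneracy,
negation necessity) hold under controlled conditions, not that absolute
scores transfer to hospital data.

## Evaluation harness

Splits are patient-grouped 70/10/20: patients are shuffled by seed and
greedily assigned to the split with the largest remaining note deficit, so
no patient crosses splits and realized sizes track targets to patient
granularity. Precision, recall and F1 are exact rational computations with
the degenerate conventions P = R = F1 = 0 when undefined (recorded in
report metadata). AUC is the Mann–Whitney probability with midrank ties —
equal in value to trapezoidal ROC integration but directly checkable by
pair enumeration. Cohen's kappa supports the simulated second annotator.
Model comparison uses the 1-df chi-squared on the 2x2 table of per-note
correctness (model x correct), computed by the closed form without
continuity correction, with a Fisher-exact fallback flagged when an
expected cell drops below 1; pooled-across-phenotypes and per-phenotype
versions are both reported because either construction is defensible.
Decision thresholds are chosen on the validation split by maximizing F1
(lowest threshold among maximizers).

## Problem sizes used by the test suite

The shipped tests exercise the stack at sizes chosen for statistical
power: planted-phrase recovery on ~1,000 notes (prevalence 0.2,
misspelling rate 0.1, decoy rate 0.3); embedding-proximity properties on
2,000 short notes; width ablations on 400-note bigram/unigram-signal
corpora over 3 seeds; pooled-embedding degeneracy on 1,200 notes of ~2,400
tokens with AUC read on the held-out 30% (~360 notes, null sd ~0.04);
negation ablation over 5 seeds of 300 notes; split integrity on 1,610
single-note patients. Embedding pre-training uses k = 50, window 5, 5
negatives, and 2–8 epochs depending on how much embedding quality the
property under test actually needs.

## Known limitations

The SGNS trainer is single-threaded and deterministic but implements no
frequent-word subsampling or hierarchical softmax. The dictionary tagger
resolves overlaps only by longest match. The negation detector has a fixed
trigger list and token-window scope with no sentence segmentation. The CNN
trains one phenotype at a time; joint multi-phenotype training, recurrent
or attention models, and text+concept hybrid inputs are deliberately out
of scope. Whether feature-map biases should be shared per width or per
filter is not settled by the architecture description we follow; this
implementation uses one bias per filter.
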