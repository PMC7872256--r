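---
title: "Semi-supervised transfer learning for low-resource NER: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised transfer learning for low-resource NER: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Biomedical named entity recognition (NER) locates mentions of genes,
chemicals, diseases or species in tokenized text. Modern sequence taggers
need thousands of labeled sentences, but word-level annotation by domain
experts is expensive, so a practitioner typically has a *small* labeled
subset of their corpus, a *large* unlabeled remainder, and access to large
automatically ("silver-standard") annotated corpora from related domains.
`ssner` implements a three-stage recipe for exactly this situation:

1. **Pre-train** a tagger on a large annotated source corpus (possibly
   rule-annotated and noisy);
2. **Fine-tune** it on the few labeled target sentences;
3. **Self-train** on the unlabeled remainder: predict, keep sentences the
   model labels with very high confidence as pseudo-labeled training data,
   retrain, and repeat until nothing clears the confidence bar.

Entities are encoded per token with the BIO scheme (`B` first word of an
entity, `I` continuation, `O` outside); the package deliberately predicts
*untyped* entities only, which is what makes pre-training corpora with
different entity inventories usable as a source domain.

## The tagger

The model is a BiLSTM-CRF: frozen word embeddings feed two stacked
bidirectional LSTM layers, a linear projection produces per-token label
scores ("emissions"), and a linear-chain conditional random field scores
whole label paths

$$s(y) = t_{\text{start}, y_1} + \sum_{i} e_{i, y_i} + \sum_{i>1} t_{y_{i-1}, y_i} + t_{y_n, \text{stop}},
\qquad P(y \mid x) = \frac{\exp s(y)}{\sum_{y'} \exp s(y')},$$

with explicit virtual start/stop states in the transition matrix. The
partition function is computed by the forward recursion in log space
(`crf_log_partition()`), decoding by Viterbi (`viterbi_decode()`, ties
broken toward the lower label index so decoding is deterministic), and
training minimizes the negative sequence log-likelihood with Adam.

Defaults follow the reference setup for full-scale corpora: 200-d frozen
embeddings, two layers of 300 units per direction, batch size 128,
learning rate 1e-4. Early stopping watches entity-level exact-F1 on a
held-out validation split after every epoch and stops after `patience`
epochs without improvement — 5 during pre-training, 10 during fine-tuning —
restoring the best-validation weights. We restore rather than keep the
final epoch because the stopping rule itself only says when to *stop*;
restoring the best epoch is the standard completion of that rule.

The per-sentence confidence that drives self-training is the
length-normalized sequence log-likelihood of the predicted path,
exponentiated:

$$\mathrm{conf}(x) = \exp\!\left(\frac{\log P(\hat y \mid x)}{n}\right) \in (0, 1],$$

i.e. a per-word geometric-mean probability. Exponentiating keeps the
default threshold of 0.9975 interpretable as "99.75% average confidence
per token". For the all-zero (uninformative) model the confidence is
exactly $1/3$, the uniform probability over the three BIO labels, which
the test suite asserts.

### Numerical and implementation choices

* The encoder (embedding lookup, LSTM layers, emission projection and
  their gradients) runs in single precision in C++ (RcppArmadillo), which
  roughly halves training time on one CPU; the CRF layer — forward
  recursion, forward–backward marginals, Viterbi — is double precision, so
  its outputs match brute-force path enumeration to 1e-8, which the test
  suite checks on random instances.
* Minibatches are seeded shuffles grouped into length buckets (batches
  hold sentences of near-equal length, and batch order is itself
  shuffled). This is the standard bucketing trick for variable-length
  sequence batches; it changes which sentences share a batch but not the
  data seen per epoch, and it keeps padded computation low.
* Padding is masked out of states, loss and confidence; masking is exact
  because padding is contiguous at the tail of each direction's iteration
  order.
* Gradients are clipped at global norm 5.0; `max_epochs` (default 200)
  bounds training when the stopping rule never fires.
* Out-of-vocabulary embedding rows are drawn from a seeded
  uniform(−0.25, 0.25); initialization, shuffling and splitting all derive
  from explicit integer seeds, so every stage is bit-reproducible on one
  machine (asserted by the determinism tests).
* Orphan `I` tags (an `I` with no live entity) never occur in generated
  gold data, but model output can contain anything, so BIO parsing is
  lenient by default (an orphan `I` opens a span) and strict on request
  for validating human annotations.
* Corpus splits use largest-remainder rounding with ties toward the
  earlier fraction, so 1000 labeled sentences always yield exactly
  800 train / 200 validation.

## The self-training loop

Each iteration re-initializes the model from the pre-trained checkpoint
(or a fresh seeded initialization when there is none) with a fresh
optimizer, trains on the current training set, predicts on the
unsupervised set, and moves every sentence whose confidence reaches the
threshold into the training set with its predicted labels marked
`label_source = "pseudo"`. Movement is one-way: pseudo-labels are frozen
when a sentence moves (an ablation flag re-predicts them each iteration).
The gold validation split fixed at the start is never altered, so model
selection and early stopping only ever see human labels. The loop ends
when nothing moves, the unsupervised set is exhausted, or the
`max_iterations` safety cap is reached; if the last iteration still moved
sentences, one final training round on the enlarged set produces the
returned model. The returned model is deliberately the *final* one — the
per-iteration history (sentences moved, cumulative pseudo-labeled
fraction, validation/test metrics) is returned so a user can select a
best-validation iteration post hoc, but the default follows the procedure
as stated. Whether the per-iteration re-seeding (`seed + iteration`) is
part of the original procedure is unknowable; we fix it for
reproducibility, and iteration 1 uses the stage seed itself so that a run
in which nothing ever clears the threshold is weight-identical to plain
fine-tuning (asserted in the tests).

## Evaluation

Scoring is entity-level, exact and partial, in the SemEval-2013 task 9.1
style restricted to untyped entities. Per sentence, gold and predicted
spans are matched one-to-one: identical spans count *Correct*; remaining
overlapping pairs are matched greedily — largest overlap first, ties to
the left-most pair — and count *Partial*; leftovers are *Missing* (gold)
or *Spurious* (predicted). *Incorrect* exists only for entity-type
mismatches and is always 0 here. With
`Possible = Correct + Incorrect + Partial + Missing` and
`Actual = Correct + Incorrect + Partial + Spurious`:

* exact precision/recall = `Correct / Actual`, `Correct / Possible`;
* partial precision/recall = `(Correct + 0.5 Partial) / Actual`,
  `(Correct + 0.5 Partial) / Possible`;
* F1 is the harmonic mean, and any 0/0 ratio is defined as 0.

Counts are summed over the corpus before the ratios are taken (micro
aggregation), matching how a single figure per dataset is normally
reported. The greedy pairing order and the one-to-one restriction are our
committed interpretation: the published scheme names the categories but
not a pairing algorithm, and one-to-one matching with a deterministic
order makes the score independent of sentence order (asserted as a
permutation-invariance test, along with the conservation identities
above and `partial >= exact`, and a cross-check against an independent
span-set scorer).

## The synthetic corpus generator

Every experiment in the package runs without downloads on seeded synthetic
corpora that reproduce the *statistical skeleton* of real biomedical NER
data:

* background tokens drawn Zipf-like (exponent 1.1) from a background
  vocabulary (default 500 types);
* multiword entities (lengths 1–3, weights 0.55/0.30/0.15) drawn from
  lexicons of entity strings built over a reserved entity-word pool
  (default 400 words, 300-entry lexicons), with a configurable fraction of
  the target lexicon shared with the source lexicon — real source/target
  corpus pairs show unique-entity overlaps from about 9% to 68%, and
  `overlap_statistic()` measures the realized value (case-folded exact
  string match, our committed convention);
* an entity-word density dial with presets mirroring real corpora
  (`benchmark-like` 0.05, `semmed-like` 0.27, `medmentions-like` 0.41);
  insertions are Poisson per sentence, calibrated so the corpus-level
  entity-word fraction matches the dial in expectation, and entities are
  placed at distinct slots so gold labels are never ambiguous;
* silver-standard corruption for the source corpus: per entity, omission
  with one rate and a one-boundary ±1-token shift with another (shifts
  never collide with neighboring spans and never empty a span); the
  default source preset uses 10% omissions and 5% boundary shifts;
* **synthetic pre-trained word vectors**: each word vector is
  $\sqrt{s}\,\mu_{\text{class}} + \sqrt{1-s}\,z_w$ with one class mean for
  entity-pool words and one for background words. Real PubMed-scale
  word2vec embeddings place entity-like words in distinct regions of the
  space — that geometry is precisely why a tagger over *frozen* embeddings
  can generalize from a few hundred sentences — and the signal fraction
  $s$ (default 0.15, chosen once during design calibration) reproduces
  that property at a strength where a few hundred labeled sentences are
  *not* enough to saturate, so transfer and semi-supervision have visible
  room to act; at $s = 0$ the embedding geometry carries no class
  information at all and a frozen-embedding tagger can only memorize
  individual training sentences.

The generator's job is testability, not linguistic realism. It does not
emulate: ambiguous entity mentions (background and entity vocabularies
are disjoint), spelling variants and abbreviations, document-level
context, nested or discontinuous entities, or class-imbalanced entity
types. Consequently, passing the package's directional checks shows the
*machinery* behaves as described (transfer helps when lexical knowledge
transfers; confident pseudo-labels add usable coverage; the threshold
trades iterations against pseudo-label volume) — it does not certify
effect sizes on real corpora.

## Desk-scale study conditions

The heavy experiments use a reduced tagger — 50-d embeddings, 64 hidden
units per direction — with batch size 32 and learning rate 3e-3,
`max_epochs` 40, and the standard patience values (5 pre-train /
10 fine-tune). The paper-scale optimizer settings (batch 128, lr 1e-4)
are matched to corpora of 10^5–10^6 sentences; at a few hundred sentences
they give only a handful of optimizer steps per epoch, far too few to
converge before the early-stopping window closes, so the desk-scale
configuration scales the step size and batch size to the corpus. Problem
sizes: pre-training source of 1000 sentences (density 0.27, silver
noise); target corpora of 1000 sentences for the learnability check
(800 train / 200 validation), 1500 for the self-training scenarios
(labeled subsets of 250 and 500, the rest unlabeled, iteration cap 6),
2500 for the labeled-size sweep (250/500/1000/2000), and 2000 with 250
labeled for the loop-invariant checks; test sets of 400 sentences. All of
these were fixed once, before the acceptance suite was written, and are
not tuned per run.

## Known limitations

* The tagger is word-level only: no character convolutions, no subword
  models, no transformer arm; entity types are not predicted.
* Confidence is a single scalar per sentence (geometric-mean path
  probability); alternative geometries (e.g. arithmetic mean of per-token
  marginals) can be computed from the exposed CRF primitives but are not
  built in, and the 0.9975 default was adopted for this geometry.
* Whether one predicted span may give partial credit to several gold
  spans is interpreted as "no" (one-to-one matching).
* BIOES or typed BIO input is not auto-converted; map to plain B/I/O
  before reading.
* Single precision in the encoder means gradients are accurate to about
  1e-3 relative — ample for SGD-family training, but numerical gradient
  checks must use directional differences at matching tolerances.
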