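---
title: "Mining consumer health vocabularies by supervised embedding projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining consumer health vocabularies by supervised embedding projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chvmine)
```

## The problem

Clinical terminologies (ICD-10, SNOMED, UMLS) name concepts the way
professionals do; patients on health forums use colloquialisms, typos and
abbreviations for the same concepts. A consumer health vocabulary (CHV)
bridges the two, and maintaining one is a continuous mining task: given a
professional term, find the consumer expressions that denote it in a large
forum corpus, with a human reviewer making the final call. `chvmine`
implements the model side of that loop: it proposes, for each professional
term, a ranked list of candidate consumer terms; reviewers accept or reject;
accepted pairs become supervision for the next round.

## Model

**Pretraining.** A corpus of tokenized messages (tokenization is upstream
and pluggable — the package never segments text itself) is preprocessed:
URL-like tokens become `URL_TOKEN`, and tokens occurring fewer than
`minCount` times (default 30, strictly less-than) become `UNKNOW_TOKEN`.
Embeddings `E` (`v × e`) are then trained unsupervised. Four method families
are provided behind one contract — CBOW and skip-gram with negative
sampling, GloVe, and a subword (character n-gram) skip-gram. These are
compact single-threaded reference implementations in C++ (no third-party
trainer is wrapped); they are deterministic given a seed, which the
published multi-threaded tools deliberately are not. Default
hyperparameters: window 5, 5 epochs, 5 negative samples.

**Projection.** The adapted space is defined by a trainable `S` (`s × e`,
`s < e`): the adapted vector of word `M` (one-hot) is `P = S·E·M`, and `E`
stays fixed throughout. Two properties motivate this factorization: the
small `s × e` parameter count matches the small supervision sets CHV work
has (a few hundred pairs), and every word's adapted vector moves with `S`,
including words never seen in supervision. `S` is initialized uniformly at
random on `[-a, a]` with `a = sqrt(6/(s+e))` — a symmetric, scale-stable
bound. `expandProjection()` grows `s` across review iterations while
keeping the already-learned rows bit-identical. Setting `s = 0` selects a
log-linear baseline: a single row of elementwise feature weights scoring
raw-`E` similarities with the same training loss, the natural floor for
the projection-size sweep of `runExperimentGrid()`.

**Supervision.** For each query, its labeled synonyms receive desired ranks
1..k ordered by corpus frequency (ties lexicographic). Supervision is used
in both directions by default (professional→consumer and consumer→
professional), since both query directions are meaningful at retrieval
time. The monitored objective is the ranking loss — the summed (absolute,
optionally squared) displacement between each synonym's current rank by
adapted-space cosine and its desired rank — which is zero exactly when all
synonyms sit at their desired positions, and is not differentiable.

**Surrogate.** Training instead minimizes the squared gap between a
synonym's adapted-space similarity and the similarity value at its desired
rank (`surrogateLoss()`, with `surrogateGradient()` its exact analytic
gradient; both are verified against finite differences in the tests). Two
numerical refinements, both documented here because they decide whether
training works at all on realistic geometry:

1. *Tie-clearing targets.* The target value at the desired rank is computed
   over the **other** candidates, plus a small margin (default 0.01, capped
   at 1). Without this, the synonym's own similarity becomes the target the
   moment it ties the occupant of its slot, the loss reaches zero, and the
   deterministic tie-break (higher corpus frequency first) keeps the more
   frequent distractor — usually a context word — above the synonym
   forever.
2. *Gradient renormalization.* When a query's neighborhood saturates
   (many candidate cosines within 1e-3 of each other — the normal state of
   a tight topical cluster), the squared loss and the cosine gradient both
   vanish, and plain SGD at any fixed rate is inert. The optimizer is
   therefore Adam (default rate 0.003), and the per-pair gradient is
   divided by `2|t − cos| + 1e-3`, turning the effective pull into an
   absolute-difference one that stays O(1) until the rank is claimed.

Two regularizers control what the small supervision set cannot:
an orthonormality penalty `λ‖SSᵀ − I‖²` (default `λ = 0.03`) pulls `S`
toward a partial isometry, which both prevents the trivial collapse of the
surrogate (all similarities → 1) and preserves raw-space geometry where
supervision carries no signal; and Polyak tail averaging of `S` over the
last half of the epochs damps the oscillation of late iterates. Per epoch,
the pool's adapted vectors and all targets are refreshed once (per-step
refreshing would cost a full pool sort per update for no observed benefit),
then one pass of mini-batch (32) updates runs; the epoch's surrogate loss,
ranking loss, training MRR and optional held-out MRR are logged
(`writeTrainingLog()` emits JSON lines).

The candidate pool for training is the top-1000 most frequent tokens plus
all seed-pair members, excluding the placeholder tokens and the query
itself; end-user retrieval (`rankCandidates()`) defaults to the full
vocabulary minus placeholders. `E` is bit-identical before and after
`fitProjection()`; a test-only `updateEmbeddings` flag propagates gradients
into a copy of `E` so the suite can demonstrate that joint updating hurts
held-out retrieval when supervision is scarce — the reason the fixed-`E`
design exists.

## Evaluation

`meanReciprocalRank()` scores a set of queries by the reciprocal rank of
the first relevant synonym (0 when none is returned; a synonym absent from
a truncated list counts as a miss, the standard MRR convention).
`evaluateProtocol()` samples evaluation pairs without replacement
(reproducibly), keeps them out of any training in the same run, and
evaluates professional→consumer by default with a flag for the reverse.
`runExperimentGrid()` produces the before/after table over embedding
methods × dimensions, and the projection-size sweep including the `s = 0`
log-linear baseline.

## The synthetic fixture

Real forum crawls are rarely redistributable, so the generator
(`generateCorpus()`) builds corpora with the statistical structure the
method relies on: each concept has one professional token, consumer
variants, and a dedicated context-token set (in real data: the diseases,
symptoms and drugs that surround a diagnostic term); a message mentions one
entity embedded in its concept's context, with a `noiseRate` fraction of
slots drawn from a Zipfian background vocabulary. Consumer mentions are
emitted as a fixed typo variant with probability `typoRate` (the analogue
of character-level misspellings); a fraction `orphanRate` of consumer
tokens get private context sets and no professional partner, giving the
entropy detector something to detect. Tokens are synthetic symbols
(`P007`, `C007_1`, `X007_3`) so the gold structure is auditable.

Defaults — the study conditions for all shipped tests — are 20 concepts ×
2 synonyms, 5000 messages of 12 tokens, context sets of 8, `noiseRate`
0.2, `typoRate` 0.05, `orphanRate` 0.1. A 20% off-topic token rate is a
moderate, realistic contamination level for forum text; 0.1 or lower makes
the task unrealistically clean. The pipeline trains 50-dimensional
skip-gram vectors (5 epochs) and a 40 × 50 projection for 150 epochs; at
this scale the full generate→embed→fine-tune→evaluate cycle runs in ~10 s
on one CPU, so multi-seed robustness checks stay cheap. The projection
size keeps 80% of the embedding dimension: a sweep over `s` with
`runExperimentGrid()` shows that at
small `e` aggressive reduction destroys more raw retrieval quality than
the supervision can restore, while the supervised tilt transfers to
held-out concepts at large `s`. Training supervision in the pipeline also
includes the generator's typo-variant pairs for training-side concepts —
typos are precisely one of the consumer-term classes a CHV collects — and
held-out concepts contribute nothing to training.

What the fixture does **not** emulate: natural-language morphology (so the
subword trainer's n-grams carry less signal than on real text), polysemy,
thread structure, topic drift, and class imbalance between concepts.
Passing tests on it show that the machinery — preprocessing, training,
ranking, evaluation — behaves as designed on data with planted synonym
structure; they do not certify retrieval quality on any real corpus.

## Numerical choices and degenerate inputs

* Similarity sorting breaks ties by corpus frequency (descending), then
  token (C-locale lexicographic): ranks are a strict total order and every
  run is reproducible bit for bit.
* Zero-norm vectors raise `"degenerate vector"` errors rather than
  returning NaN cosines; placeholder rows in a candidate pool are tolerated
  (they can never win a ranking).
* `preprocessCorpus()` is idempotent; placeholders are never re-masked.
* "Less than 30" and "over 1000" frequency rules are strict inequalities.
* Entropy uses natural logarithm; plain softmax of raw cosines
  (temperature 1) by default, configurable — no temperature is baked in.
* All seeds are plain 32-bit integers; the C++ trainers use an internal
  splitmix64 generator rather than the standard library's
  implementation-defined distributions.

## Known limitations

* No real forum corpus ships with the package; every quantitative claim in
  it refers to the synthetic study conditions above.
* Architectures of this family are sometimes drawn with a hidden layer
  between the projection layers; with no principled choice of its size or
  nonlinearity for this task, none is implemented. A single `S` shared by
  the professional and consumer sides keeps similarity symmetric and is
  the default (a separate target-side projection would break that
  symmetry for no demonstrated gain).
* Multi-token terms must be merged (`mergeTerms()`) before vocabulary
  building; the package does not learn phrase boundaries.
* With supervision sets of a few dozen pairs, held-out improvement has
  high variance — single-seed results should never be interpreted without
  a multi-seed replication, which is how every shipped check is written.
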