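---
title: "Weighted-vote ensembles for biomedical NER: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-vote ensembles for biomedical NER: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nervote)
```

## The model

Biomedical named-entity recognition is cast as BIO sequence labeling: each
token receives `O`, `B-<type>` or `I-<type>`. Suppose N base classifiers
have been trained, classifier m with overall cross-validated strict-match
F-measure $F_m$, and for each token $t$ classifier m emits a hard label
$op(t, m)$. The ensemble is parameterized by a non-negative weight matrix
$V \in \mathbb{R}^{N \times O}$ over the O output labels. The combined
score of class $c$ at token $t$ is

$$ f(c, t) \;=\; \sum_{m \,:\, op(t,m) = c} V(m, c)\, F_m $$

and the joint decision is $\arg\max_c f(c, t)$, taken independently per
token; conflicting entity boundaries between classifiers are resolved
implicitly by this per-token argmax. The working hypothesis is that a
classifier's reliability differs across output classes, so a single global
weight per classifier is too coarse: a per-class weight lets the ensemble
trust each classifier exactly where it is strong. Only hard labels are
combined — no probabilistic calibration or per-token marginals.

The weights are learned by maximizing the cross-validated performance of
the decoded ensemble. The corpus is split into k sentence-level folds
(default 5); for a candidate V, each fold's held-out tokens are decoded by
weighted voting and scored with strict matching; the fitness is the mean of
the k fold F-measures. This fitness is piecewise constant in V — only the
order of the products $V(m, c) F_m$ matters — which shapes several choices
below.

### Strict-match evaluation

An entity chunk is a maximal BIO span; a predicted chunk is correct iff its
sentence, left boundary, right boundary, and type all equal a gold chunk's.
Recall = correct/gold, precision = correct/predicted, F is their harmonic
mean; all on the percent scale and reported to two decimals. An `I-X` token
without a preceding `B-X`/`I-X` of the same type ("orphan") starts a new
chunk, the conlleval-compatible convention; `extract_chunks()` takes a flag
to drop orphans instead, isolating the convention in one place. Token
indices are 0-based and spans are closed intervals.

### Decode tie rule

The label alphabet orders entity labels lexicographically with `O` last.
Ties among positive scores resolve to the earliest alphabet label
(deterministic and reproducible); a token whose every class scores zero —
no weighted vote at all — decodes to `O`, so zero-information ties never
invent entities. The all-zero rule matters: with non-negative weights the
GA can (and does) switch individual vote channels off entirely by driving
weights to exactly 0 via mutation clamping.

## The genetic algorithm

A chromosome is the row-major flattening of V: N·O genes, initialized
i.i.d. uniform on [0, 1]. Defaults: population P = 100, G = 50
generations. Each generation:

1. **Fitness** of every chromosome (mean fold-wise strict F, cached by
   chromosome bytes — decoding dominates cost and populations contain many
   duplicates).
2. **Elitism**: the best-ever chromosome is archived outside the population
   and re-injected each generation in place of the current worst, so the
   best-so-far trace is non-decreasing by construction.
3. **Selection**: roulette wheel, probability proportional to fitness
   (uniform if all fitnesses are zero).
4. **Crossover**: P/2 parent pairs drawn with replacement; normal
   single-point crossover gated per pair with adaptive probability
   $\mu_c = k_1 (f_{max} - f')/(f_{max} - \bar f)$ for pairs whose larger
   fitness $f'$ is above average, else $k_3$; $k_1 = k_3 = 1$.
5. **Mutation**: per gene with adaptive probability
   $\mu_m = k_2 (f_{max} - f)/(f_{max} - \bar f)$ above average, else
   $k_4$; $k_2 = k_4 = 0.5$. A mutated gene is replaced by a draw from a
   Laplace distribution centered at the old value with scale
   $\delta = 0.1$, then clamped to [0, 1]: any point of the range is
   reachable while mass concentrates near the old value
   ($E|X - \mu| = \delta$, median $\mu$).

The adaptive forms are the canonical Srinivas–Patnaik (1994) expressions;
the fitness arguments are taken on the [0, 1] scale (percent / 100), a monotone
conversion that leaves selection unaffected.

Points where the scheme admits more than one reading, and what this
package does:

* **Degenerate population** ($f_{max} = \bar f$): $\mu_c = k_1$,
  $\mu_m = k_2$. On plateau-heavy fitness landscapes whole populations tie;
  falling back to the full rates re-opens exploration instead of freezing.
* **Mutation basis for offspring**: an offspring's fitness is unknown when
  mutation is applied, so it inherits the evaluation basis of its
  originating parent (first offspring → first parent). Variants (larger or
  smaller parent fitness) were examined and search quality was comparable.
* **Elite handling**: replace-worst re-injection (rather than archive-only)
  keeps the best solution in the breeding pool; configurable in principle,
  fixed here for reproducibility.
* **Gene clamping**: initialization draws genes in [0, 1]; mutation could
  leave that range. Clamping preserves the weight semantics and the
  decode's scale invariance, and — because the fitness depends only on
  products $V(m,c) F_m$ — loses no expressiveness. It also gives positive
  probability to exactly-zero weights, which some optima require (see
  limitations).
* **Weights for `O`**: `O` receives a learned weight column like any other
  label. The alternative (fixed weight 1) is representable by the same
  machinery and was not needed.

## Feature suite

`extract_features()` emits the families enabled in a `feature_template()`,
given `feature_resources` built from the training portion only:

* context words in a window of radius 0–3 and their left-to-right n-grams
  (n ≤ 2); PoS/chunk windows when those columns exist; out-of-sentence
  positions yield `<s>`/`</s>` placeholders;
* prefixes/suffixes up to 4 characters of the current word;
* length > 5 indicator; infrequent-word indicator (< 10 training
  occurrences) — the conventional thresholds for these feature families;
* word shape (capitals→`A`, lowercase→`a`, digit runs→`0`, others kept) and
  word class (additionally digits→`O`, other characters→`-`, then runs
  squeezed). Note the word-class output alphabet contains the capital
  letter `O`, so the mapping is deliberately not idempotent — the mapping
  definition takes precedence;
* 18 orthographic categories (capitalization/digit patterns, hyphen, Roman
  numerals, stop words, nucleotide-like `ATGC` strings, Greek letter
  names); categories are not mutually exclusive;
* head nouns: final unigrams/bigrams of training entity mentions with
  frequency ≥ 2 (the cutoff mirrors the informative-word rule);
* trigger verbs: words immediately preceding training mentions, frequency
  ≥ 2;
* informative words: candidates are words inside multiword mentions minus
  digit/number/symbol tokens; words with < 2 inside-entity occurrences are
  dropped; survivors are binned by
  NEweight(w) = (occurrences inside entity spans) / (total occurrences)
  into five equal-width classes over (0, 1]. The ratio form is the natural
  measure of how exclusively a word marks entities, and equal-width binning
  is the simplest reproducible stratification; both are design choices of
  this package rather than canonical definitions;
* content words: the 10 most frequent (ties lexicographic) filtered,
  lower-cased unigrams within ±3 tokens of entity tokens, counted across
  sentence boundaries; the per-token feature marks which vocabulary words
  occur in the token's context. Because gold entity locations are unknown
  at test time, the package supports a two-pass mode: a first pass without
  the feature, then a second pass that uses the first-pass predictions to
  define entity contexts;
* unknown token: at test time, "surface unseen in training"; at training
  time the bit is randomized — Bernoulli(0.5) from the seeded run RNG,
  drawn once per token occurrence, so that the learner sees the feature
  active on a representative mix of seen words (0.5 is the uninformative
  choice);
* dynamic features: the previously assigned tags up to depth 3 — gold tags
  while training, predictions while decoding, so extraction never reads the
  gold label of the current or a future token.

The "normalization" stem is a deliberately crude suffix-stripper
(lower-case, strip plural `s`/`es` and `ing`/`ed`, collapse digits):
the intent is a stable equivalence class, not linguistic correctness.

## Model bank

Base labelers are pluggable: any backend exposing `fit` and `predict` over
corpora and templates can register. Two reference backends ship: a
dependency-free memorizing baseline (most frequent training label per
surface, unseen → `O`) and a multinomial naive-Bayes classifier over the
extracted feature bag with greedy left-to-right decoding, which is
feature-sensitive, so template variations produce genuinely different
ensemble members. In the literature, CRF and margin-based sequence labelers
are the usual base learners for this kind of ensemble; the ensemble layer
implemented here is agnostic to the backend, and the properties tested
concern the ensemble, not the learners. Folds are sentence-level (sequence labelers need intact
sentences), sizes differ by at most one, and all classifiers in a bank
share identical folds — otherwise the ensemble fitness is ill-defined.
$F_m$ is the strict F over the concatenated held-out predictions, on the
percent scale, computed by the same scorer used everywhere
(`strict_match_scores()` is the single source of truth).

## Synthetic data

The generator emulates the corpus properties the ensemble machinery is
sensitive to: sentences of 6–12 tokens; entity mentions of 1–4 tokens at a
Poisson-distributed rate per sentence; per-type surface dictionaries in
which a configurable fraction of tokens carries capital/digit/hyphen marks
("IL-2"-style); trigger verbs placed before mentions at a configurable
rate; PoS-like and chunk-like auxiliary columns. Simulated classifiers
corrupt gold labels per token according to a per-class reliability profile
a(m, j), with errors uniform over the other labels or, alternatively, a
boundary-jitter rule (flip B/I role; promote `O` to a random `B-`) that
stresses the strict-boundary penalty. Per-token corruption can break BIO
validity exactly as real taggers do, which exercises the orphan handling of
the decode/score path.

What the generator does **not** emulate: real lexical statistics, document
structure, annotation-guideline ambiguity, or correlated errors between
classifiers (profiles are independent given the gold label). Passing tests
therefore demonstrate the correctness and the mechanism of the ensemble —
per-class weighting exploits complementary reliability — not performance
levels on real corpora.

## Problem sizes and numerical choices

The test suite runs its heavier checks at deliberately moderate scale,
chosen as the smallest sizes at which the studied effects are
unambiguous: oracle-equivalence sweeps use 500 random sentence pairs and
1000-token decode comparisons; GA-recovery and dominance studies use
250–300 generated sentences (≈ 2000–2600 tokens), 5 folds, populations of
50 and 30 generations, repeated over 10 seeds. The exact-optimum oracle
for two-classifier banks enumerates all realizable decision patterns of
the vote-product comparisons — fitness is piecewise constant in V, so this
enumeration equals the supremum over all real weight matrices and
dominates any finite grid. Fitness evaluations are cached by chromosome
bytes; all randomness flows through a single integer seed per run, and
reruns are byte-identical.

## Known limitations

* When some disagreement patterns never occur (e.g. perfectly reliable
  profiles leave certain vote conflicts unrealized), the corresponding
  weight entries are unconstrained at the optimum and drift freely on the
  fitness plateau; only constrained weights are interpretable.
* Optima that require a vote channel to be switched off entirely live on a
  measure-zero set (exact zeros); they are reachable only through mutation
  clamping, and recovery within a fixed generation budget is less reliable
  than for interior optima.
* The naive-Bayes backend is a per-token classifier with greedy decoding,
  not a structured sequence model; its absolute F-measures on hard corpora
  will trail CRF-class learners. The ensemble layer is indifferent to this.
* Strict matching only; the partial-credit variants of shared-task
  evaluations are intentionally out of scope.
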