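---
title: "Methods: opinion mining and utilization factor analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: opinion mining and utilization factor analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opinionpulse)
```

`opinionpulse` implements a complete inference chain for studying public
opinion on a health topic in a social-media stream alongside utilization
statistics: topic tracking by active learning, sentiment classification with
a maximum-entropy model and an opinion-aware knowledge graph, the yearly
Opinion Polarity Ratio, online LDA topic mining, and Lasso / Bayesian-network
factor attribution of visit counts. Because the motivating corpora
(a national forum stream, a national statistics panel, hospital visit
records) are proprietary, the package ships seeded synthetic generators that
emulate their statistical structure with known ground truth; every claim the
package makes is checked against that ground truth.

## The synthetic study conditions

### Post corpus

`gen_corpus()` produces a multi-year stream in a synthetic language:
space-delimited tokens over four pairwise disjoint vocabularies — topic
*entities* (nouns), *positive* and *negative* opinion words (adjectives) and
off-topic *filler* — plus two signed emoticon sets and expressive
punctuation. The design choices that matter:

* **Exact composition, not sampling.** Yearly sentiment labels (and the
  on-topic flag) are allocated by largest-remainder rounding against the
  configured proportions and then shuffled across posts. The configured
  trend is therefore the *exact* ground truth of every generated corpus, so
  a calibrated trend ratio is a deterministic target rather than a random
  one.
* **Topical density.** On-topic posts carry 2–5 entity mentions (mean 3.5)
  among 8–16 tokens; a post about a topic realistically names it several
  times. Polar posts carry 1–3 opinion words of the matching polarity;
  neutral posts carry none. Off-topic posts draw from filler only.
* **Calibrated headline trend.** The shipped `headline_trend.yaml`
  configuration (10 years × 2,000 posts/year) sets the yearly
  negative/positive ratio to rise geometrically from 0.60 to 0.60 × 2.33,
  with a constant neutral share of 0.35, so the true end-to-start OPR ratio
  is exactly 2.33-fold. The calibration constants live in the YAML file,
  not in code.
* Timestamps are uniform within each year (no intra-year structure is
  modeled); user ids are generated but carry no behavioral structure.

What the generator does *not* emulate: natural-language morphology and
segmentation ambiguity, topic drift inside a year, sarcasm or mixed-polarity
posts, and correlated user behavior. Passing tests therefore demonstrate the
*analysis logic* under clean, separable conditions, not robustness to real
noisy language.

### Utilization panel

`gen_panel()` emulates a national statistics panel: 34 regions × 11 years
(2004–2014) × 30 named candidate factors. Factors are standard normal;
log-visit weights are `u_r + beta' x + eps` with a region size effect
`u_r ~ N(0, 0.3)`, the sparse ground truth `beta` (GDP proxy 0.6, education
proxy 0.4, all others zero) and noise `eps ~ N(0, 0.1)`. Each year is then
rescaled so the national total follows
`base_total * visits_growth^(year - 2004)` **exactly**, with
`visits_growth = 2.41^(1/10)`. We chose exact rescaling over a purely
multiplicative error model deliberately: the national yearly total is the
published, deterministic quantity the analysis treats as ground truth, while
the cross-sectional dependence of visits on the factors — which is what the
Lasso and the Bayesian network must recover — is untouched by a per-year
scale factor.

### Visit-age records

`gen_visit_records()` draws ages from a mixture of uniform bands whose
default weights put the modal mass at 25–35 (32%) and a secondary
early-childhood 0–8 mode (18%) that exceeds the neighboring 9–15 band (4%),
with the remaining mass spread over the adult bands. The default band
weights are the package's own choice of a plausible age profile with those
two qualitative features.

## Text preprocessing

`extract_proper_nouns()` protects user mentions (`@name`), URLs
(`scheme://...`) and email addresses with placeholder tokens before
tokenization; the patterns are the package's own (the upstream description
of this step names no concrete regular expressions). `tokenize_text()`
splits on whitespace, separates `! ? . , ; :` into single-character tokens,
and keeps emoticons and protected tokens whole. POS tagging is a lexicon
lookup: the synthetic language has an exact tag lexicon, so a statistical
tagger would add an untestable dependency without changing anything
downstream, which only consumes the coarse classes NOUN / ADJ / VERB / EMO /
PUNCT / PROPER / OTHER.

## Topic tracking

`track_topic()` is a pool-based active-learning loop: train a binary
classifier on the labeled set, score the pool, query a batch, move it to the
labeled set with oracle labels, retrain; after the budget is spent the final
classifier labels the whole corpus at a 0.5 threshold. Choices:

* **Selection strategy.** The default is *uncertainty sampling* (query the
  posts nearest the decision boundary). A literal "largest score" rule —
  exploitation, querying the most confidently positive posts — is kept as
  an option, but it cannot be the default for a binary pool: once the
  classifier is any good, the posts it scores highest are genuinely
  on-topic, so the loop queries almost no negatives, the boundary is never
  sharpened, and held-out F1 collapses relative to uncertainty sampling
  under identical budgets.
* **Classifier.** The loop is the contribution; the classifier is a
  pluggable two-function contract. The default is a class-balanced
  ridge-penalized logistic regression fitted along a decreasing penalty
  path (predictions at λ = 10⁻³): deterministic, calibrated, and — the
  property that matters under uncertainty sampling — dense. A sparse (L1)
  fit looks attractive for bag-of-tokens features but interacts badly with
  boundary-focused querying: the labeled set covers only the token subset
  the queried posts happen to contain, L1 zeroes every other equally
  informative token, and posts carrying only unseen tokens fall back to
  the intercept, with seed-dependent collapses of held-out F1. Ridge keeps
  every observed token's weight; the acceptance suite verifies the loop's
  F1 across ten paired seeds against a random-labeling baseline. The
  elastic-net mixing is exposed for anyone who wants the sparse variant,
  and a linear-kernel SVM backend (`classifier_svm()`) is also provided.
* Batch size 10, budget 20 iterations, threshold 0.5 are package defaults
  (no values are prescribed upstream); ties in selection scores break by
  post id for determinism.

## Sentiment classification

`classify_corpus()` runs the full chain:

1. **Lexicon bootstrap** (`bootstrap_lexicon()`): nouns with document
   frequency ≥ 2 become entity candidates; adjectives/verbs co-occurring
   within a 3-token window of an entity candidate in ≥ 2 posts become
   sentiment-word candidates. This is a deterministic stand-in for
   topic-model-based lexicon induction, which upstream work uses only to
   speed up expert labeling.
2. **MaxEnt training** (`train_maxent_iis()`): the multinomial log-linear
   model `p(c|d) ∝ exp(Σ_j λ_{j,c} g_j(d))` over per-post counts of each
   lexicon word, signed emoticon counts and `!`/`?` counts, trained on a
   stratified sample of 200 expert labels per class (ground truth in the
   synthetic setting) by improved iterative scaling. Every instance is
   padded with a slack feature so the feature total is constant — the IIS
   requirement — and the update
   `δ = log(empirical / expected) / M` provably never decreases the
   training log-likelihood; features never observed with a class receive a
   capped negative update, which preserves the guarantee. 200 labels per
   class is deliberate: the bootstrap produces on the order of two hundred
   features, and a much smaller expert sample leaves the model
   substantially less accurate — with errors that, being *caused* by
   specific noise features, feed back coherently into the graph stage
   below.
3. **Opinion-aware knowledge graph** (`build_okg()`): nodes are lexicon
   tokens; node polarity is `(n₊ − n₋) / (n₊ + n₋ + γ)` over
   MaxEnt-labeled posts containing the token (γ = 1); edges are within-post
   co-occurrence counts.
4. **Stance propagation** (`propagate_stance()`): each node's polarity is
   augmented by one round of damped neighbor-weighted averaging
   (one round keeps the operation deterministic and bounded; no iteration
   scheme is prescribed upstream), a post's score is the sum over matched
   nodes, and labels follow a neutral band: positive above τ = 0.1,
   negative below −τ, neutral otherwise — including posts matching no node.

Two gates on node contributions are the package's own additions, and both
exist for identified failure modes rather than taste. A *magnitude gate*
(`min_node_polarity = 0.25`) stops opinion-neutral entity tokens from
absorbing the corpus-level positive/negative imbalance. A *significance
gate* (`z_gate = 3`, requiring `|n₊ − n₋| ≥ z √(n₊ + n₋)`) addresses a
subtler circularity: a filler token that the MaxEnt model happened to weight
positively causes the posts containing it to be labeled positive, so the
token's own graph counts then "confirm" the error; frequency alone cannot
distinguish this from a genuine opinion word, but count significance can.
The smoothing constant and the propagation damping are separate parameters
(`gamma`, `damping`), both exposed.

The graph is the final arbiter by default; `arbiter = "maxent"` is an
ablation switch. A unanimous seed sample (e.g. an all-neutral corpus)
short-circuits the MaxEnt stage and expands the single observed class.

## Opinion Polarity Ratio

`opr()` implements the two-branch ratio exactly as defined: `n₋/n₊` when
`n₊ ≠ 0`, and the smoothed `(n₋ + δ)/(n₊ + δ)` only when `n₊ = 0`, with
`0 < δ ≤ 1` and δ = 1 by default. An `always_smooth` flag provides the
variant that smooths both branches. `opr_series()` bins by calendar year,
excludes neutral posts from both counts, and emits empty years with zero
counts (their ratio comes from the smoothed branch). `trend_ratio()` is the
last period's value over the first's.

## Topic mining

`lda_online()` is stochastic variational LDA: per-document variational
E-steps, then a topic-word update with step size `ρ_t = (τ₀ + t)^{-κ}`.
Words never seen before are appended to the vocabulary before each update
(initialized from the same seeded Gamma(100, 100) draw as the rest of the
topic-word matrix, so new dimensions are not symmetric across topics).
With κ = 0 a single full-corpus batch reduces to one batch variational EM
step, which the tests assert. Defaults K = 10, α = 1/K, η = 0.01, κ = 0.7,
τ₀ = 64, minibatch 256. Positive and negative subsets are scored against one
shared model fitted on all on-topic posts and then ranked per subset
(`top_topics()`, top-5 with top-10 words); sharing one model keeps the two
co-occurrence graphs (`topic_cooccurrence()`, presence threshold θ = 0.2)
on a common topic space.

## Factor analysis

`preprocess_panel()` restricts to 2004–2014, drops zero-variance columns
with a warning, standardizes the factors and uses `log(visits)` as the
response, so coefficients are comparable impact coefficients per standard
deviation. `lasso_cd()` is cyclic coordinate descent with soft-thresholding
on `(1/2n)‖y − Xβ‖² + λ‖β‖₁`; `lasso_cv()` picks λ at the minimum mean
10-fold cross-validation error (not the one-standard-error rule) over a
50-point log grid with a seeded fold shuffle. The tests pin the solver to
the OLS limit at λ = 0, the orthonormal soft-threshold closed form, and an
independent solver on the same objective.

`discretize_panel()` cuts every variable into quantile tertiles (columns
with fewer distinct values are binned by value). `learn_bn()` is greedy
hill climbing over add/delete/reverse single-edge moves maximizing the BDeu
score with equivalent sample size 1.0, in-degree capped at 2, optional
naive-Bayes initialization with visits as the class; accepted moves strictly
increase the score and the result is always a DAG. `influential_factors()`
returns the Markov blanket of `visits`. Tertiles, the score, and the search
are package choices; the upstream description names tool knobs without
reporting chosen values.

## Pipeline

`run_pipeline()` executes generate → tokenize → track → classify → OPR →
topics → factors in dependency order, writes one plain-text artifact set per
stage plus a JSON report index with provenance (a hash of the scientific
configuration, the seed, the package version), and fails a stage cleanly
when its upstream artifact is missing. Identical configurations reproduce
byte-identical reports. `summarize_report()` renders the trend figure
(OPR vs. visits, dual axis), the coefficient bar chart and the age
histogram, and lists missing components instead of failing.

## Problem sizes and determinism

The test suite exercises the chain at the sizes the package treats as its
reference desk-scale conditions: the full headline corpus (10 × 2,000
posts) for the trend-recovery check across 10 seeds, 5,000-post corpora for
the sentiment stack, a 10,000-post/year corpus for the generator-proportion
invariant, 2,000 documents for topic separation, and the 374-row panel for
factor recovery across 10 seeds. All randomness flows through explicit
integer seeds; generators restore the caller's RNG state.

## Known limitations

* The synthetic language is separable by construction; none of the reported
  accuracies transfer to real text.
* Stance propagation runs one neighbor-averaging round, not to a fixed
  point; deep graph structure is not exploited.
* The Bayesian network treats region-years as exchangeable observations and
  ignores temporal autocorrelation; the year trend enters the Lasso stage
  as unexplained variance.
* Visits are modeled at the national-share level; no per-capita
  normalization is attempted.
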