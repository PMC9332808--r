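---
title: "Methods: comparing vaccine discourse across social media platforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing vaccine discourse across social media platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxtalk)
```

## The analysis

`vaxtalk` implements a cross-platform content-analysis pipeline for
vaccine-related social media comments. The study design it supports is:
collect the comments under a common topic from several platforms, keep the
N most-reacted-to ("top") comments per platform, label each comment with
one category from a fixed codebook (here one positive category and
fourteen anti-vaccine argument themes), check that the manual labeling is
reliable, extract per-category keywords to validate that the categories
are semantically coherent, and then ask whether the platforms differ in
the distribution of anti-vaccine arguments.

The pipeline makes the usual assumptions of this design: each comment
carries exactly one category (single-label coding), the reaction count is
a single non-negative integer regardless of the platform's reaction
vocabulary, and top-comment selection is a deterministic function of the
reaction counts. Ties at the selection cut are broken by stable input
order — reaction data rarely ties at the cut in practice, but a
deterministic rule is required for reproducibility, so the rule is ours
and is documented here rather than left to sort-order chance.

## Interrater reliability

Manual category coding is validated with Krippendorff's alpha for nominal
data. All pairable label values (items with at least two non-missing
labels) are pooled into a coincidence matrix: an item with *m* labels
contributes weight 1/(*m* − 1) for each ordered pair of its labels. With
`o_ck` the coincidences, `n_c` the category marginals and *n* the total,

- observed disagreement `D_o = (Σ_{c≠k} o_ck) / n`,
- expected disagreement `D_e = (Σ_{c≠k} n_c n_k) / (n (n − 1))`,
- `alpha = 1 − D_o / D_e`.

Alpha is 1 for perfect agreement, near 0 for chance-level coding, and can
be negative under systematic disagreement. Only the nominal metric is
implemented because the codebook categories are unordered; interval and
ordinal metrics would impose a distance the categories do not have. The
pairable-values rule is a robustness extension: fully double-coded samples
never trigger it. Raw percent agreement is provided as a cross-check but
is not chance-corrected, which is why alpha is the headline statistic.
Degenerate grids in which every pairable value falls in a single category
have `D_e = 0`; alpha is undefined there and the package raises an error
rather than returning a number.

## Keyword relevance

After preprocessing, the relevance of term *w* to category *k* is

```
r(w, k | λ) = λ · log(φ_kw) + (1 − λ) · log(φ_kw / p_w)
```

where `φ_kw` is the term's probability within the category's token pool
and `p_w` its probability in the whole corpus. The first component favors
frequent-in-category terms; the second (the lift) down-weights terms that
are frequent everywhere. Defaults and conventions:

- `λ = 0.5`, weighing both components equally.
- Natural logarithm. The base only rescales scores by a constant factor,
  so rankings are base-invariant (tested); the choice is immaterial where
  it matters.
- Pairs with `φ_kw = 0` are not scored at all rather than scored −∞: the
  formula is undefined at zero and "relevance of a term to a category"
  only makes sense for terms the category actually uses.
- Ties in the score break lexicographically by term, again determinism
  over an unstated original convention.
- `top_n = 6` keywords per category by default, matching the length of
  the published per-category keyword lists; categories with no tokens
  yield empty lists, not errors.

### Preprocessing

Token documents are produced by: (i) markup stripping — URLs, whole
`#hashtag` tokens, `@mentions`, and emoji (matched by Unicode property
classes `\p{So}`/`\p{Sk}` plus variation selectors, zero-width joiners and
keycap marks, not by an enumerated emoji list); (ii) translation through a
pluggable seam whose default is the identity (machine-translation backends
can be registered, but are external services and are not reimplemented);
(iii) lowercasing and deletion of digit, punctuation and symbol
characters, whitespace tokenization, and stopword removal; (iv)
lemmatization through a pluggable, pure term→term contract whose default
is the identity. The step order — stopword filtering *before*
lemmatization — follows the listed order of the steps and is fixed
because the two orders differ for inflected stopwords. The stopword list
is a fixed English function-word list versioned inside the package
(`inst/extdata/stopwords_en.txt`) so results cannot drift with external
library updates. Hashtag tokens are deleted whole, not de-hashed.

The default identity lemmatizer is a deliberate choice, not a gap: the
downstream statistics depend only on token counts, the synthetic test
corpora use uninflected vocabulary, and a POS-aware lemmatizer for real
text plugs in through `register_lemmatizer()` without touching the
pipeline.

## Platform comparison

Per platform, the anti-vaccine categories' counts are normalized by the
platform's total anti-vaccine comment count, giving fixed-length
frequency vectors (N = 14 under the default codebook); the positive
category is excluded because the question is how *anti-vaccine argument
mixes* differ. Pairwise similarity is the cosine of these vectors, which
for non-negative vectors lies in [0, 1] and is invariant to the
normalization itself (cosine on raw counts equals cosine on frequencies;
tested to 1e-12).

Homogeneity of the category distributions across platforms is tested with
the Pearson chi-square test of homogeneity, without continuity
correction — the omnibus table is much larger than 2×2, and using the
same statistic in the omnibus and post-hoc stages keeps the two
comparable. Before testing, categories are removed by the
zero-expected-cell rule: a category is dropped iff it has a zero count on
two or more platforms, which is exactly the condition under which some
pairwise platform subtable has a zero row total and hence an expected
count of exactly 0. Removed categories are always reported; the report
never drops a category silently. Post-hoc, all C(C−1)/2 platform pairs
are tested on their pair subtables (re-pruned by the same rule) and
p-values are Bonferroni-adjusted by multiplication capped at 1, which
makes the same decisions as the α/m threshold while keeping reportable
adjusted p-values. The significance level defaults to 0.05 and is
configurable. Platform order everywhere is first-appearance order in the
input, recorded in the outputs.

## The synthetic corpus generator

The raw annotated comment data sets this analysis targets are typically
shared only on request, so the package ships a generator that emulates
their statistical structure and makes every stage testable end-to-end:

- **Sampling frame**: four platforms × 250 comments by default, matching
  the 1,000-comment top-comment design.
- **Labels**: drawn per platform from a 15-category probability vector.
  The default is the published marginal category fractions on every
  platform — an exchangeable, homogeneous configuration that serves as
  the null for calibration experiments. `preset_platform_profiles()`
  provides the heterogeneous configuration: tiktok freedom-heavy
  (category 1), facebook/twitter government/safety/efficacy-heavy
  (categories 2–4, near-identical to each other, with twitter very
  slightly more government-heavy so that the most-dissimilar pair is
  unique in expectation), instagram testing/bragging-heavy (categories
  5–6). The preset's per-category deviations sum to zero across
  platforms, so its across-platform marginal equals the published
  fractions exactly and its expected anti-vaccine share is 0.729.
- **Text**: token sequences, not natural language. Comment length is
  Poisson with per-platform means 30/32/12/22 words (the published
  per-platform mean lengths); each token is, with probability 0.3, a
  draw from the label's 6-keyword pool (the published per-category
  keyword lists) and otherwise a draw from a 200-word filler vocabulary
  of deterministic consonant-vowel pseudo-words. The 0.3 planting rate
  keeps planted keywords clearly recoverable while leaving filler terms
  in the majority, which is the regime the relevance score is designed
  for.
- **Reactions**: discretized log-normal (`sdlog = 1.5`) with per-platform
  `meanlog` chosen so the mean reaction counts match the published
  per-platform reaction totals (≈160/28/139/130 per comment); the heavy
  tail makes top-N selection non-degenerate.
- **Annotations**: coder 1 records the true label; coder 2 copies it
  with probability `agreement_q` (default 0.95) and otherwise draws
  uniformly from the other 14 categories. This symmetric-uniform error
  model is a modeling choice, not a claim about any real coders; at the
  default it produces alpha values in the low 0.9s over 100 items,
  consistent with the high-agreement regime reported for this kind of
  double coding.
- **Determinism**: every stochastic call runs under the config seed, so
  corpora are byte-identical across runs and platforms.

What the generator does *not* emulate: natural-language syntax and
inflection, code-switching and translation noise, correlation between a
comment's category and its length or reaction count, multi-label
ambiguity, and coder biases that depend on the category. Passing tests on
synthetic data therefore demonstrate the correctness and calibration of
the statistical machinery under the declared model — not the validity of
any substantive claim about real platforms.

## Calibration and test design

The test suite checks the omnibus test's type-I error by generating 500
homogeneous corpora at the study size (250 comments per platform) and
requiring the rejection rate at α = 0.05 to fall inside the exact
binomial 99% acceptance region around 0.05. At this sample size several
categories have small expected counts (the rarest has 5 expected comments
in 1,000), so the rarest categories are often pruned and the Pearson
statistic runs slightly conservative — observed rejection rates sit near
0.03, inside but toward the lower edge of the acceptance region. This is
a property of the chi-square approximation under sparse categories, and
it is visible here precisely because the generator reproduces the
published (sparse) category frequencies rather than a convenient dense
configuration.

Power is checked with 200 replicates of the distinct-platform preset
(rejection in well over 95% of replicates), and the cosine structure —
facebook/twitter the most similar pair — is checked both analytically on
the preset's expected vectors and as the modal outcome across replicates.
Keyword recovery requires at least 80% of each category's planted pool in
the category's top-10 relevance list; categories that drew no comments at
a given seed have no list (the rarest category has probability 0.005 per
comment and is empty in roughly 0.7% of corpora), so the check applies to
categories present in the corpus. Problem sizes throughout (500 null
replicates, 200 power replicates, 2,000-item reliability samples for the
copy-model comparison, exhaustive agreement grids up to 3 items × 2
coders and random grids up to 8 items × 3 coders × 3 categories) were
chosen to make Monte-Carlo error small relative to the tolerances while
keeping the full suite comfortably fast on one CPU.

Oracles are independent of the code paths they check: alpha is compared
against a brute-force enumeration of every ordered pairable pair, the
2×2 chi-square against the closed form `n(ad − bc)² / (r₁r₂c₁c₂)`,
relevance scores against hand-evaluated values, and the simulated
double coding against a closed-form expectation of alpha under the
copy-error model.

## Known limitations

- Only the nominal alpha metric is implemented; no bootstrap confidence
  intervals for alpha.
- No effect sizes (e.g. Cramér's V) and no alternatives to Bonferroni
  (Holm, FDR) in the post-hoc stage.
- The relevance score is count-based; it does not model burstiness or
  document length, and categories with very few tokens produce noisy
  rankings.
- The published headline inferential values of the motivating study
  design (an alpha of 0.919, an omnibus chi-square of 357, the pairwise
  p of 0.344, and the observed cosine matrix) depend on raw annotated
  comments that are not publicly deposited; they are context, not
  recomputable targets, and nothing in the package pretends otherwise.
  What is recomputable from the published summary tables — the 1,000
  grand total, the 72.9% anti-vaccine share, the 0.271/0.156 category
  fractions, the 2.5 facebook/tiktok length ratio — is recomputed
  exactly by `reference_corpus()` plus the ordinary pipeline functions.
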