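# vaxtalk

Cross-platform analysis of vaccine discourse on social media.

`vaxtalk` is an R toolkit for the kind of infodemiology study that asks: *do
users of different social media platforms argue against vaccination in
different ways?* It takes tables of comments (platform, text, reaction
count, optional category label) plus a codebook of content categories —
here, one positive category and fourteen anti-vaccine argument themes — and
carries the analysis from raw comment tables to the comparative statistics:

- **Corpus model** — readers/writers for CSV/JSONL comment tables,
  top-N-by-reactions selection (e.g. the 250 most-reacted comments per
  platform), per-platform summaries, and category-by-platform contingency
  tables.
- **Preprocessing** — markup stripping (URLs, #hashtags, @mentions, emoji),
  a pluggable translation seam (identity by default), lowercasing,
  digit/punctuation removal, stopword filtering, and pluggable
  lemmatization.
- **Interrater reliability** — Krippendorff's alpha for nominal data from a
  coincidence matrix, `α = 1 − D_o/D_e`, with the pairable-values rule for
  missing labels, plus raw percent agreement as a cross-check.
- **Keyword relevance** — per-category keyword extraction with the
  λ-weighted relevance score
  `r(w, k | λ) = λ·log φ_{k,w} + (1 − λ)·log(φ_{k,w}/p_w)`,
  where `φ_{k,w}` is the term's within-category probability and
  `φ_{k,w}/p_w` its lift over the corpus-wide probability (λ = 0.5 by
  default).
- **Platform comparison** — per-platform anti-vaccine category frequency
  vectors (length 14), pairwise cosine similarity
  `cos(x, y) = Σxᵢyᵢ / (√Σxᵢ² · √Σyᵢ²)`, the chi-square test of
  homogeneity with the zero-expected-cell category-removal rule, and
  Bonferroni-corrected post-hoc pairwise tests.
- **Synthetic data** — a fully seeded generator of labeled comment corpora
  and double-coded annotation samples with the statistical structure the
  analysis assumes (platform-specific category frequencies, planted
  per-category keywords, platform-specific comment lengths, heavy-tailed
  reactions), so every stage is testable without any data download.

## Worked example

The `"preset"` profile simulates four platforms with distinct anti-vaccine
argument mixes (a freedom-heavy tiktok-like platform, near-identical
government/safety-heavy facebook- and twitter-like platforms, a
testing/bragging-heavy instagram-like platform) whose across-platform
marginal matches the published category fractions of a 1,000-comment
annotated data set:

```r
library(vaxtalk)
bundle <- run_pipeline(run_config(corpus = "preset", seed = 42))

bundle$reliability
#> <vax_reliability> Krippendorff's alpha (nominal) = 0.870  [D_o = 0.1100, D_e = 0.8465, items = 100]

cat(sprintf("Anti-vaccine share: %.1f%%\n", 100 * bundle$anti_share))
#> Anti-vaccine share: 72.6%

bundle$homogeneity
#> <vax_homogeneity> chi2 = 80.53, df = 39, p = 0.0001032

round(unclass(bundle$similarity), 3)
#>           facebook instagram tiktok twitter
#> facebook     1.000     0.901  0.859   0.980
#> instagram    0.901     1.000  0.947   0.862
#> tiktok       0.859     0.947  1.000   0.846
#> twitter      0.980     0.862  0.846   1.000

subset(bundle$keywords, category_id == 1)
#>   category_id rank      term  relevance
#>             1    1   freedom -0.4698445
#>             1    2     never -0.4886134
#>             1    3    choice -0.5024647
#>             1    4  everyone -0.5652336
#>             1    5 vaccinate -1.1097141
#>             1    6       get -1.1268120
```

Reading the output: 100 simulated double-coded items give an alpha of
0.870 (high agreement, consistent with the generator's 95% coder-copy
rate); about 73% of the simulated top comments are anti-vaccine; the
omnibus chi-square rejects homogeneity of the anti-vaccine argument
distributions across platforms (p ≈ 1e-4, after removing categories that
would produce zero expected counts); the cosine matrix shows the
facebook/twitter pair as most similar (0.980) and tiktok/twitter as least
(0.846); and the top keywords recovered for category 1 are exactly its
planted freedom-of-choice vocabulary. `render_report(bundle)` lays all of
this out as a Markdown report and `write_bundle(bundle, "out/")` writes the
keyword TSV, similarity CSV, and homogeneity JSON.

`reference_corpus()` builds a deterministic corpus realizing the published
per-platform summaries (250 comments each; mean lengths 30/32/12/22 words)
and marginal category counts (1,000 comments, anti-vaccine share 72.9%)
exactly, for fixture arithmetic on those tables.

## Scope

The package analyzes comment tables; it does not scrape platforms, call
platform APIs, or perform machine translation (the translator seam defaults
to identity and accepts registered backends). Raw annotated comment data
from published studies is typically available only on request; the
synthetic generator and the published summary tables stand in for it
throughout the tests.
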