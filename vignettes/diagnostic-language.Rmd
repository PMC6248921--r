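---
title: "Diagnostic vocabulary, positivity and stereotype profiles: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic vocabulary, positivity and stereotype profiles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natlex)
```

`natlex` implements a pipeline for asking which words, emojis and emoticons
are diagnostic of one population's social-media output relative to
another's, how positive that diagnostic vocabulary is, and how personality
profiles inferred from it compare with stereotype and self-report profiles.
This vignette explains the statistical machinery, the tunable parameters,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## The weighted log-odds model

The core statistic is the log-odds ratio with an informative Dirichlet
prior. For an n-gram $w$ with count $y_{wi}$ among $n_i$ total n-gram
tokens in corpus $i$ (and $y_{wj}$, $n_j$ in corpus $j$), the prior
pseudo-counts are the pooled corpus itself: $\alpha_w$ is the combined
count of $w$ and $\alpha_0 = \sum_w \alpha_w$ the combined total. The
smoothed log-odds difference is

$$
\delta_w \;=\;
\log\frac{y_{wi}+\alpha_w}{\,n_i+\alpha_0-y_{wi}-\alpha_w\,}
\;-\;
\log\frac{y_{wj}+\alpha_w}{\,n_j+\alpha_0-y_{wj}-\alpha_w\,},
\qquad
\sigma^2(\delta_w) \;\approx\; \frac{1}{y_{wi}+\alpha_w} +
\frac{1}{y_{wj}+\alpha_w},
$$

and each n-gram gets a standardized score $z_w = \delta_w / \sigma$.
Shrinking toward the pooled corpus means a rare token needs a much larger
observed imbalance than a frequent one to reach the same $|z|$ — the
property that makes the statistic robust where raw odds ratios and tf-idf
style effect sizes over-reward rare words. Two corpora that use a token at
identical counts and totals give $z = 0$ exactly, and swapping the corpora
negates every score.

Two modelling notes:

* **Standardization.** `loridp_z()` divides $\delta$ by the standard
  deviation $\sqrt{\sigma^2}$. Some presentations of the statistic typeset
  $\delta/\sigma^2$; because the selection thresholds used downstream
  (±1.96, and the Bonferroni cutoff below) are quantiles of a standard
  normal, only the $\delta/\sigma$ form is coherent, and it is the default.
  `sqrt_variance = FALSE` computes the other form for comparison.
* **Prior strength.** With `prior_scale = 1` (the default, matching the
  construction above) the prior carries as much weight as the data, so
  $\delta_w$ is a strongly shrunken estimate of the true log-odds shift —
  roughly a third of it in balanced two-corpus designs. Ranks are
  preserved (shrinkage is monotone at a given frequency), which is why the
  package's recovery tests assert Spearman rather than absolute agreement,
  and why stimulus selection by $|z|$ is unaffected. Users who want
  $\delta$ on the log-odds scale can pass a small `prior_scale`.

Selection uses a two-tailed Bonferroni-corrected normal cutoff at
family-wise level $\alpha$ over $m$ = the number of n-grams actually
scored (unigrams and bigrams pooled): `bonferroni_threshold(m, alpha)` =
$\Phi^{-1}(1-\alpha/2m)$. At $\alpha = 0.01$ and $m = 2{,}761{,}118$ the
cutoff is $5.9$. Ties in $|z|$ are broken by pooled frequency and then
lexicographically so that stimulus lists (`top_k_stimuli()`) are
deterministic.

## Filtering and bot detection

`filter_records()` applies inclusion rules to tweet-style records: tweet
and profile language must match the target language, the geotag must fall
in a half-open bounding box (`region_spec()`), and the author must have
strictly more than 10 records in the input. Every exclusion is attributed
to the first failing criterion, so the counts in `filter_report()` add up.

Bot detection uses two content-based signals:

* **Pairwise dissimilarity** — for up to `max_sample = 500` texts per
  user, the mean over all unordered pairs of
  $1 - |\mathrm{LCS}(a,b)| / \max(|a|,|b|)$, where LCS is the longest
  common *contiguous* substring in Unicode characters (computed in C++;
  quadratic per pair). Templated accounts share long substrings and score
  low; diverse human text scores near 1. The normalization by the longer
  text and the use of contiguous substrings (not subsequences) are design
  choices: they bound the metric in $[0,1]$ and target repeated templates
  rather than diffuse character overlap. The metric is computed on raw
  (not case-folded) text.
* **URL rate** — mean count per tweet of scheme- or `www.`-prefixed
  tokens.

A user is flagged when mean dissimilarity $< 0.8$ **or** URL rate
$\ge 1$ (both thresholds config-exposed; the inclusive URL bound is
deliberate). Users with a single text bypass the dissimilarity criterion —
the metric is undefined there — but remain subject to the URL rule, and in
practice are removed anyway by the more-than-10-tweets rule.

## Tokenization and lexical filtering

A unigram is: any emoji (including variation selectors, skin-tone
modifiers, zero-width-joiner sequences and two-letter flag sequences), any
punctuation sequence exactly matching the emoticon lexicon, or any maximal
run of two or more letters, digits, hyphens or underscores, case-folded.
Hashtags, @-mentions and URLs are stripped first; everything else (single
characters, unmatched punctuation) is dropped. Emoticon matching is
longest-match and happens before punctuation is discarded — that ordering
is what lets `:)` survive. Word tokens are lower-cased; emoticons are kept
verbatim because the lexicon match is exact.

`build_counts()` counts unigrams and contiguous bigrams per corpus side;
bigrams never span tweet boundaries. `apply_lexical_filters()` then runs,
in a fixed order chosen so the steps compose idempotently:

1. **Spelling merge** — variants mapped to a canonical (US) form and
   counts summed, so "centre" and "center" become one entry *before* any
   count threshold is applied.
2. **Stopwords** — stopword unigrams removed, and bigrams containing a
   stopword removed. Bigrams are formed on the full token stream first and
   filtered afterwards, which preserves content bigrams such as
   "feel like" while still removing function words.
3. **Gazetteer** — an n-gram exactly matching a place name is removed
   unless every constituent word is on the common-word exception list
   ("river bend" survives, "greater london" does not): place names are
   trivially diagnostic of a region and would otherwise dominate.
4. **Minimum count** — items whose frequency *pooled over both sides* is
   below `min_count = 3` are dropped. The pooled reading (rather than
   per-side) is a deliberate resolution of an ambiguity: thresholding
   per side would delete exactly the strongly one-sided items the method
   exists to find.

## Rank bins and positivity

Each side's selected items are ranked by $|z|$ and split into
`n_bins = 10` contiguous rank deciles (`rank_bins()`); leftover items when
the count is not a multiple of ten go to the earliest (most diagnostic)
bins. `join_lexicon()` attaches token positivity scores — word lexica on a
1–9 scale, emoji lexica on a −1..1 scale, never mixed; a token appearing
in two word lexica gets the arithmetic mean (`merge_lexica()`). Unscored
tokens are dropped and per-bin coverage is reported. `compare_bins()` then
runs one Welch two-sample t-test per matched bin pair (unequal sizes and
variances after lexicon joins are the rule, hence Welch rather than the
pooled-variance test), multiplies p by the number of bins (capped at 1),
and reports Cohen's d with pooled SD, sign A − B, plus t-based 95%
confidence intervals on the bin means.

## Survey statistics

Ratings arrive as long-format records (rater, condition, facet code
N1..C6, value 1–5, response duration). `clean_responses()` removes raters
under 60 seconds, keeps only the first submission per rater × facet, and
drops missing selections cell-wise. Profiles and Welch facet tests
(Bonferroni × 30) use cell-wise deletion; `icc_1k()` and
`within_subject_se()` require rater-wise complete data, matching how such
exclusion counts are usually reported.

* `difference_vector()` returns the 30 per-facet mean differences
  (condition A − condition B, i.e. US − Canada when A is the
  American-words condition) in the fixed facet order N, E, O, A, C. The
  bundled reference table of standardized self-report (NEO-PI-R)
  differences was published with trait rows ordered N, E, A, O, C; the
  fixture normalizes it to the canonical order once, at creation, because
  a silent order mismatch is the most likely reproduction bug in this kind
  of comparison.
* `compare_difference_vectors()` reports Pearson r with
  $t = r\sqrt{28}/\sqrt{1-r^2}$ on 28 df. It is symmetric and invariant to
  separate affine rescaling of each vector.
* `icc_1k()` is the one-way random-effects, *average-measures* intraclass
  correlation with facets as targets and raters as interchangeable
  measurements: $(MS_B - MS_W)/MS_B$ from the one-way ANOVA across facets.
  It is computed from mean squares directly. Note that under pure noise
  the estimator is slightly negatively biased ($E[1/MS_B]$ convexity), so
  "no structure" shows up as values scattered a little below zero, not at
  exactly zero.
* `within_subject_se()` implements the Cousineau–Morey construction:
  center each rater at their own mean, add back the grand mean, take the
  per-facet SE of the centered data and inflate it by $\sqrt{k/(k-1)}$
  with $k = 30$ facets. The adjusted SE is invariant to per-rater offsets;
  with no rater effects it coincides with the naive SE (the inflation
  exactly undoes the deflation that centering induces).

## What the synthetic generator emulates — and what it does not

The corpus generator (`corpus_spec()`, `generate_corpus_pair()`) draws a
shared vocabulary with Zipf-distributed base probabilities
(`zipf_exponent = 1.08`, the heavy-tailed regime word-frequency studies
report and the regime the Dirichlet prior is designed for), mixes emoji
and emoticon tokens into the vocabulary (5% and 2% of types by default),
assigns negative-binomial tweet counts per user (mean 30, dispersion 10)
and truncated-Poisson tweet lengths (mean 11 tokens, capped at 23 — the
token budget of a 140-character message), and populates language tags and
side-consistent geotags. Defaults are sized so that a default corpus is
large enough to exercise every pipeline stage in seconds; tests that need
corpus-scale behaviour (≥10⁶ pooled tokens) scale `n_users_per_side` up
explicitly.

Ground truth is planted on *draw probabilities*, not counts: a planted
token's log-odds on side A are shifted by exactly the specified amount,
and the leftover probability mass is spread proportionally over the
unplanted tokens. Exact zero shift for every unplanted token is
impossible — probabilities must renormalize — so unplanted tokens move by
a small shared term, roughly the log of the rescale factor (about 0.05
when the planted tokens carry a few percent of the corpus). Bias planted
this way keeps the truth well defined under multinomial sampling, which
post-hoc count editing would not.

Bot accounts (`bot_spec()`) instantiate a fixed template with small slot
variation and append URLs at a given mean rate, reproducing by
construction the two signals the bot filter keys on. Survey tables
(`survey_spec()`, `generate_survey_table()`) draw discretized truncated
normals on the 1–5 scale; the latent mean of each facet is calibrated by
root finding so that the *discretized* rating has the requested mean
(naive rounding of a latent normal biases the mean by up to ~0.07 near the
scale edge, which would swamp the recovery checks). SDs are matched only
on the latent scale. Default targets are the published facet summary
shipped with the package, with 200 raters per condition and the observed
fast-responder (~3%) and missing-cell (~1.5%) rates.

The generator deliberately does **not** model tweet syntax, topics,
hashtag ecology, retweet networks, dialect geography, or rater response
styles beyond a per-rater additive offset. Consequently, passing tests
demonstrate that the *pipeline* recovers planted frequency, positivity and
rating structure under realistic marginal distributions — they do not
certify behaviour on real social-media text, where tokenization edge
cases, topic confounds and spatial correlation are harsher.

## Numerical and degenerate-input conventions

Identical seeds give byte-identical generator output (all randomness runs
under a locally scoped seed). Welch tests on two zero-variance samples
return p = 1 when the means agree and p = 0 otherwise rather than erroring.
Bins or facets with fewer than two scored items are skipped with a warning
and `NA` statistics. A stimulus request larger than the surviving
vocabulary returns everything, with a warning. `pairwise_dissimilarity()`
on fewer than two texts is `NA` ("insufficient data"), and such users pass
the bot filter on that criterion. Exclusion stems remove simple
inflectional variants (stem + s/es/ed/ing/er/ers/in/in') and any bigram
containing a matching constituent. Region boxes are half-open so adjacent
regions partition space without double-counting boundary points.

## Known limitations

* The published corpus-scale numbers (tens of millions of tweets, specific
  z-scores for individual words, the d ≈ 0.6 word and d ≈ 1.3 emoji
  positivity gaps, ICC ≈ .98) are not reproducible without the original
  (undeposited) corpora and the full third-party lexica; the package
  reproduces the printed-table arithmetic exactly and validates the
  corpus-scale machinery on synthetic ground truth instead.
* The emoji recognizer covers the standard pictograph ranges and sequence
  forms, not the full Unicode emoji property data; exotic sequences may
  tokenize as separate parts.
* The bundled stoplist, spelling map, emoticon lexicon and gazetteer are
  compact samples; serious applications should supply their own resources
  via the loader arguments or the CLI flags.
* Point-in-region supports rectangular boxes only; polygon regions would
  need an external geometry dependency.
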