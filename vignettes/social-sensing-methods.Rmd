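---
title: "Methods: population-normalised engagement and Bayesian net sentiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-normalised engagement and Bayesian net sentiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

opinionpulse measures two things from a geotagged social-media corpus
about vaccines: how much each population group talks about the subject
(engagement) and how positively it talks about it (sentiment), both as
daily series that can be compared across US states, discussion topics and
imputed race groups. This vignette is the package's own account of the
models, the knobs that matter, and the choices made where the design was
genuinely open.

## The engagement model

Raw daily post counts are not comparable across regions: populous states
dominate trivially. Social-media volume grows sublinearly with population,
so the package normalises by a power of population:

$$\mathrm{PES}_{r,d} = \frac{N_{r,d}}{\mathrm{pop}_r^{\beta}}$$

where $N_{r,d}$ is the number of vaccine-related posts from region $r$ on
day $d$ and $\beta$ is the volume--population scaling exponent. Empirical
estimates of $\beta$ lie between 0.67 and 0.78; the package defaults to
0.725 and treats it as data, not something to estimate (`compute_pes()`,
`daily_pes()`). Two consequences the tests exploit: a region with
population $2^{1/\beta}$ times larger needs exactly twice the posts to
score equally, and if corpora are generated with the same exponent used
in scoring, expected PES is identical across regions regardless of size.

Denominators per stratification: state PES uses state population, race
PES national race populations, national and topic PES the national total
(a topic has no population of its own; this is recorded in the run
manifest). The imputed race label `unknown` has no denominator and is
excluded from race PES. The packaged population tables are 2010 census
figures; the table is an input, so any consistent vintage can be
substituted.

## The sentiment model

Each post carries one of three polarities. For a stratum-day with counts
$(n_1, n_2, n_3)$ (positive, neutral, negative) and total $N$, the
observed proportions are $\theta_i = n_i / N$ and the net sentiment score
is

$$\mathrm{PSS} = \theta_1 - \theta_3 \in [-1, 1].$$

On low-volume days the raw PSS is noisy, so the package models the
three-class proportions with the conjugate Dirichlet--multinomial. The
prior for day $d$ is built from the preceding week:

$$\alpha_i = b + w \sum_{d' \in \text{window}} n_{i,d'}$$

with baseline $b = 1$ and weight $w = 1/7$ by default; the posterior adds
the day's counts, its mean gives the point PSS in closed form, and
equal-tailed Monte-Carlo quantiles of $\theta_1 - \theta_3$ give the
credible interval (`build_prior()`, `posterior_update()`,
`pss_credible_interval()`, `daily_pss_series()`).

Design choices that were genuinely open:

* **Prior construction.** "Informative prior from last week's sentiment"
  admits many readings; the pseudo-count form above is the minimal
  conjugate one. $b = 1$ makes the empty-history case the balanced
  non-informative prior $(1,1,1)$, and $w = 1/7$ makes a full week of
  history worth about one average day of data, so the prior stabilises
  quiet days without dominating busy ones. Both are config keys.
* **Window semantics.** "Preceding week" is implemented as the trailing 7
  days strictly before the target day (not the calendar week);
  `window_days` is a parameter.
* **Equal-tailed rather than highest-density intervals**: simpler,
  deterministic given a seed, and adequate for an uncertainty band.
* **The point estimate is the posterior mean, not the Monte-Carlo mean**,
  so reruns with different `n_mc` change only the interval, never the
  point series.
* **Days with zero posts** are flagged `prior_only` and reported from the
  prior alone, never silently interpolated.

With the defaults, a day with $N = 200$ posts has posterior concentration
$\Sigma\alpha \approx 400$; intervals narrow as volume grows (checked by
simulation), which mirrors the behaviour one sees when comparing early
low-volume weeks with later high-volume ones.

Weekly summaries average the daily point PSS over consecutive 7-day
blocks anchored at the series start; empty blocks are omitted.

## Polarity classification

The pipeline's recommended mode takes polarity labels as an input column
(produced by whatever annotation tool the user trusts). For
self-contained runs the package ships a multinomial Naive Bayes
classifier over unigram bag-of-words features with additive smoothing
(`train_nb()`, `classify()`): posterior $\propto P(c)\prod_t P(t\mid c)$.
Out-of-vocabulary tokens are skipped at classification time (the training
smoothing already reserved their mass), log-likelihoods are floored at
$-745$ so `smoothing = 0` cannot produce `-Inf`, and exact ties are
broken positive > neutral > negative. Unigrams are the minimal reading of
"features"; no negation handling or continuous-score thresholding is
attempted.

## Topic tagging

Three aspects of the vaccine discussion are tagged from a keyword
lexicon: `vaccine_type` (brands), `phased_vaccination` (rollout and
administration) and `health_concern` (side effects). A topic fires iff
one of its phrases occurs as a whole-token phrase in the tokenized text —
substring matching would let the keyword *old* fire inside *golden*. The
matching rule is a documented choice (the tagging literature uses both);
the lexicon is user-replaceable CSV, and `extract_ngrams()` provides the
bigram/trigram frequency diagnostics used to validate a lexicon against a
corpus. One tweet can receive 0–3 topics. The escaped brand form
"johnson amp johnson" is kept alongside the tokenized "johnson johnson"
so both raw and HTML-escaped text match.

## Race imputation

Each post's race label is drawn from the census surname distribution of
the author's last name: surname normalised (trim, strip diacritics,
uppercase), looked up in the six-group percentage table, and one label
sampled with the row's probabilities via a fixed cumulative ordering
(white, black, api, aian, two_prace, hispanic), consuming one uniform
variate per post in input order — this makes every run replayable from
the seed. Posts with absent or unmatched surnames become `unknown` and
are reported separately. Assignment is deliberately per post, not per
author (two posts with the same surname may get different labels); a
`per_surname` mode shares one draw per distinct surname for users who
prefer consistency over faithfulness to the per-post procedure.

Rows of the surname table whose six percentages sum to more than ±0.5
away from 100 (typically census small-cell suppression) are rejected with
a warning; accepted rows are rescaled to sum to exactly 100. The packaged
example table keeps one such row on purpose so the rejection path stays
exercised.

## The synthetic study

`synth_config()` defaults define the synthetic study all tests run
against: the 2020-10-01 to 2021-05-21 window (233 days), the 48
contiguous states plus DC with 2010 populations, Poisson daily counts
around the power-law mean with `base_rate = 4.5` posts/day per million
reference population (giving a national volume of roughly 700–800
posts/day and a ~180k-post corpus, the scale of a real multi-month
geotweet study), multiplicative spikes
on the five milestone dates, a piecewise-linear polarity schedule that
jumps positive on 2020-11-09 and dips in mid-April, independent
per-aspect keyword injection (15–20% per topic), and a surname pool over
the packaged example table plus unlisted/absent entries yielding a
matched fraction around 62%, the same order as the 52% a real census
match achieves.

Poisson counts are the minimal model consistent with "volume grows
sublinearly with population"; no overdispersion is simulated. Template
texts contain no lexicon keyword (asserted by a test), so topic-tagging
precision and recall are exactly 1.0 by construction — on real text,
keyword matching will of course both miss paraphrases and fire on
negated mentions, and the synthetic corpus says nothing about that. The
generator's known ground truth (expected counts, daily proportions,
injected topics, pool mixture) is what the recovery tests compare
against; passing them shows the estimators are correct, not that the
lexicon or the classifier would perform equally on real tweets.

## Sub-periods and summaries

The study window splits into four regimes at the three milestone dates
(defaults 2020-11-09, 2020-12-14, 2021-03-12; the third milestone is only
dated "around 12 March" by public reporting, so it is a config key). A
boundary date starts the new regime. Five-number summaries use linear
interpolation of order statistics (`stats::quantile` type 7, switchable),
applied to daily PES and weekly PSS per stratum and period.

## Numerical and reproducibility notes

* All randomness flows through explicit integer seeds: the corpus
  generator, the race draw stream and the PSS Monte-Carlo each take one.
  Reruns of `run_pipeline()` with fixed seeds are byte-identical apart
  from the manifest timestamp; score files print reals with 12
  significant digits, which is also the round-trip precision contract.
* Monte-Carlo intervals use `n_mc = 20000` draws by default: quantile
  error is then well under 0.01 on the PSS scale, negligible against the
  posterior spread on realistic volumes.
* The test suite exercises the full default study (49 regions × 233
  days, ~150k posts) for the end-to-end determinism property and smaller
  windows (tens of days, 2–3 regions) elsewhere; the sizes are chosen so
  each property is measured where it is sharpest — coverage on 200 days
  at N=200/day, power-law recovery on 140–200 days at Poisson means of
  tens per day.

## Known limitations

Keyword topic tagging cannot see paraphrase or negation; the Naive Bayes
classifier is a deliberately simple stand-in for production sentiment
annotation; surname-based imputation is probabilistic at the individual
level and only meaningful in aggregate (and the `unknown` mass is large
and non-random in real data); and the correlation of sentiment with
case/vaccination series is left to the user — the pipeline aligns and
exports those series but fits no model to them.
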