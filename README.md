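# opinionpulse

Social sensing of COVID-19 vaccine opinions from geotagged posts:
population-normalised engagement scoring and Bayesian net-sentiment
estimation, with keyword topic tagging and surname-based race imputation,
for epidemiologists and computational social scientists who need
comparable daily opinion series across US states, discussion topics and
demographic groups.

## What it computes

**Public engagement score (PES).** Daily post volume normalised by a
sublinear power of population, so large and small regions are comparable:

    PES_{r,d} = N_{r,d} / pop_r^beta,   beta = 0.725 (range 0.67-0.78)

**Public sentiment score (PSS).** With daily three-class polarity counts
(n1, n2, n3) and proportions theta_i = n_i / N, the net sentiment is

    PSS = theta_1 - theta_3  in [-1, 1]

modelled as a Dirichlet–multinomial: the prior for each day is built from
the preceding week's counts (alpha_i = 1 + (1/7) * sum of window n_i,
reducing to the balanced non-informative prior (1,1,1) without history),
the posterior adds the day's counts, and equal-tailed Monte-Carlo
quantiles of theta_1 - theta_3 give a credible interval around the
closed-form posterior-mean point estimate.

Around these two scores the package provides: a trainable multinomial
Naive Bayes polarity classifier (supplying labels on input is the
recommended mode), whole-token keyword tagging of three vaccine aspects
(vaccine type, phased vaccination, health concern) with bigram/trigram
diagnostics, per-post probabilistic race assignment from census-style
surname tables, milestone-date sub-period partitioning with five-number
summaries, and a synthetic geo-corpus generator with known ground truth
that makes every stage testable without any private data.

## Worked example

The analysis scripts run the whole study on synthetic data:

```sh
Rscript analysis/01_simulate.R    # corpus + reference tables -> results/data
Rscript analysis/02_classifier.R  # optional polarity model
Rscript analysis/03_pipeline.R    # all score tables -> results/pipeline
Rscript analysis/04_summaries.R   # per-period summaries -> results/tables
```

Step 1 generates 182,875 posts over 233 days × 49 regions (2020-10-01 to
2021-05-21). Step 3 reports a 62.1% race classification rate and writes
15 artifacts. Step 4 prints, among others:

```
Weekly national PSS by sub-period (median [q1, q3]):
  period 1: +0.086 [+0.081, +0.098]
  period 2: +0.310 [+0.266, +0.318]
  period 3: +0.252 [+0.212, +0.282]
  period 4: +0.308 [+0.295, +0.369]
```

Read: before the efficacy-endpoint announcement (period 1) net sentiment
was mildly positive; it jumps after the announcement, dips while cases
peaked (period 3) and recovers as vaccination ramps up — exactly the
drift the generator injected, recovered by the estimator. The national
daily PES medians stay near 5.4e-4 across periods because the synthetic
volumes were generated with the same exponent used in scoring, which is
the normalisation working as intended.

A minimal programmatic session:

```r
library(opinionpulse)
tab <- read_surname_table(op_example("surname_race_table.csv"))
tab[tab$surname == "WASHINGTON", "black"]   # 87.53 (% Black for that surname)
compute_pes(1000, 1e6)                      # 0.04466836
pss_point(polarity_proportions(c(5, 3, 2))) # 0.3
```

## Layout

- `R/` — package code: I/O, synthetic generator, classifier, engagement,
  Bayesian sentiment, topics, race, periods, pipeline orchestrator.
- `analysis/` — the numbered study scripts shown above.
- `inst/extdata/` — small plain-text reference tables (2010 state and
  race populations, example surname distribution rows, default lexicon).
- `vignettes/social-sensing-methods.Rmd` — the methods account: models,
  assumptions, parameter choices, limitations.
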