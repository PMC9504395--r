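#!/usr/bin/env Rscript

# Step 4 — narrative summaries of the pipeline outputs.
#
# Prints the per-sub-period national engagement and sentiment summaries,
# the topic ranking diagnostics (top bigrams/trigrams), and the race
# classification rate; writes compact tables under results/tables/.

suppressPackageStartupMessages(library(opinionpulse))

stopifnot(dir.exists("results/pipeline"))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

qp <- read_daily_scores("results/pipeline/quartiles_pes.csv")
qs <- read_daily_scores("results/pipeline/quartiles_pss.csv")

cat("National daily PES by sub-period (median [q1, q3]):\n")
nat <- qp[qp$stratification == "nation", ]
for (i in seq_len(nrow(nat))) {
  cat(sprintf("  period %d: %.3e [%.3e, %.3e]\n",
              nat$period[i], nat$median[i], nat$q1[i], nat$q3[i]))
}

cat("\nWeekly national PSS by sub-period (median [q1, q3]):\n")
nats <- qs[qs$stratification == "nation", ]
for (i in seq_len(nrow(nats))) {
  cat(sprintf("  period %d: %+.3f [%+.3f, %+.3f]\n",
              nats$period[i], nats$median[i], nats$q1[i], nats$q3[i]))
}

cat("\nTopic PES medians by sub-period:\n")
top <- qp[qp$stratification == "topic", ]
print(reshape(top[, c("stratum", "period", "median")],
              direction = "wide", idvar = "stratum", timevar = "period"),
      row.names = FALSE)

manifest <- jsonlite::read_json("results/pipeline/manifest.json")
cat(sprintf("\nrace classification rate: %.1f%% (%d of %d posts)\n",
            100 * manifest$race_summary$matched_fraction,
            manifest$race_summary$n_matched, manifest$race_summary$n_total))

# lexicon validation: most frequent bigrams/trigrams in a corpus sample
tweets <- read_tweets("results/data/corpus.csv")
sample_idx <- seq_len(min(nrow(tweets), 20000))
bi <- extract_ngrams(tweets[sample_idx, ], n = 2, top_k = 15)
tri <- extract_ngrams(tweets[sample_idx, ], n = 3, top_k = 15)
cat("\nTop bigrams:\n")
print(head(bi, 8), row.names = FALSE)
write_daily_scores(bi, "results/tables/top_bigrams.csv")
write_daily_scores(tri, "results/tables/top_trigrams.csv")
write_daily_scores(qp, "results/tables/quartiles_pes.csv")
write_daily_scores(qs, "results/tables/quartiles_pss.csv")
cat("\ntables written to results/tables\n")
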