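#!/usr/bin/env Rscript

# Step 1 — build the synthetic study inputs.
#
# Generates the default synthetic geo-corpus (48 contiguous states + DC,
# 2020-10-01 to 2021-05-21, power-law daily volumes with milestone-day
# spikes, drifting polarity, injected topic keywords, known surname pool)
# plus the reference tables and stand-in daily case/vaccination series,
# and writes everything under results/data/.

suppressPackageStartupMessages(library(opinionpulse))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(seed = 20201001)
g <- generate_corpus(cfg)
cat(sprintf("generated %d posts over %d days x %d regions\n",
            nrow(g$tweets), length(cfg$dates), length(cfg$regions)))
cat(sprintf("mean daily national volume: %.1f posts\n",
            nrow(g$tweets) / length(cfg$dates)))

write.csv(g$tweets, file.path(out, "corpus.csv"), row.names = FALSE, na = "")
write_tweets_jsonl(g$tweets[seq_len(min(nrow(g$tweets), 1000)), ],
                   file.path(out, "corpus_head.jsonl"))

file.copy(op_example("state_population_2010.csv"),
          file.path(out, "state_population.csv"), overwrite = TRUE)
file.copy(op_example("race_population_2010.csv"),
          file.path(out, "race_population.csv"), overwrite = TRUE)
file.copy(op_example("surname_race_table.csv"),
          file.path(out, "surname_table.csv"), overwrite = TRUE)

# stand-in daily series: cases peak in early January, vaccinations ramp up
cases <- generate_daily_series(cfg$dates, "peaked", level = 5e4,
                               peak_date = as.Date("2021-01-08"),
                               peak_height = 2e5, width = 30,
                               noise_sd = 5e3, seed = 7)
write_daily_scores(cases, file.path(out, "cases_daily.csv"))
vax <- generate_daily_series(cfg$dates, "peaked", level = 0,
                             peak_date = as.Date("2021-04-10"),
                             peak_height = 3e6, width = 60,
                             noise_sd = 5e4, seed = 8)
write_daily_scores(vax, file.path(out, "vaccinations_daily.csv"))

cat("study inputs written to", out, "\n")
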