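#!/usr/bin/env Rscript

# Step 3 — run the full social-sensing pipeline on the simulated study.
#
# Consumes the inputs from step 1 and writes every score table (daily PES
# and PSS per stratification, weekly PSS, per-period quartiles, race
# summary, manifest) under results/pipeline/.

suppressPackageStartupMessages(library(opinionpulse))

stopifnot(file.exists("results/data/corpus.csv"))

config <- list(
  corpus = "results/data/corpus.csv",
  population_table = "results/data/state_population.csv",
  race_population_table = "results/data/race_population.csv",
  surname_table = "results/data/surname_table.csv",
  case_series = "results/data/cases_daily.csv",
  vaccination_series = "results/data/vaccinations_daily.csv",
  seed_race = 401, seed_pss = 402
)
t0 <- Sys.time()
suppressWarnings(run_pipeline(config, "results/pipeline"))
cat(sprintf("pipeline finished in %.1f s\n",
            as.numeric(difftime(Sys.time(), t0, units = "secs"))))
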