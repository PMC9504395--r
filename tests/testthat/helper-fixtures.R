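# Shared fixtures, all built in code at test time.

# the packaged census-style example table; Beyale's row sum is off 100 by
# more than the tolerance and is dropped with a warning
example_surname_table <- function() {
  suppressWarnings(read_surname_table(op_example("surname_race_table.csv")))
}

write_jsonl_corpus <- function(lines) {
  path <- tempfile(fileext = ".jsonl")
  writeLines(lines, path)
  path
}

# a minimal labelled corpus data frame
make_tweets <- function(n, date = as.Date("2020-10-01"), state = "CA",
                        text = "hello there", surname = NA_character_,
                        polarity = "neutral") {
  data.frame(
    message_id = sprintf("m%05d", seq_len(n)),
    tweet_date = rep_len(as.Date(date), n),
    tweet_text = rep_len(text, n),
    state = rep_len(state, n),
    surname = rep_len(surname, n),
    polarity = rep_len(polarity, n),
    stringsAsFactors = FALSE
  )
}

# hand-rolled corpus for the 3-document classifier examples
toy_training <- function() {
  data.frame(
    text = c("good good", "bad", "ok"),
    polarity = c("positive", "negative", "neutral"),
    stringsAsFactors = FALSE
  )
}

# write corpus + reference tables for a pipeline run; returns the config list
pipeline_fixture <- function(tweets, regions, dir,
                             race_pop = op_example("race_population_2010.csv"),
                             ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- file.path(dir, "corpus.csv")
  write.csv(tweets, corpus, row.names = FALSE, na = "")
  pop_path <- file.path(dir, "pop.csv")
  write.csv(data.frame(region = names(regions), population = regions),
            pop_path, row.names = FALSE)
  c(list(corpus = corpus, population_table = pop_path,
         race_population_table = race_pop,
         surname_table = op_example("surname_race_table.csv")),
    list(...))
}
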