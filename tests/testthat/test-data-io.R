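test_that("a JSONL record round-trips field by field", {
  path <- write_jsonl_corpus(paste0(
    '{"message_id":"m1","tweet_date":"2020-10-05",',
    '"tweet_text":"hello world","state":"NY","surname":"Chen",',
    '"polarity":"positive"}'))
  tw <- read_tweets(path)
  expect_equal(nrow(tw), 1L)
  expect_equal(tw$message_id, "m1")
  expect_equal(tw$tweet_date, as.Date("2020-10-05"))
  expect_equal(tw$tweet_text, "hello world")
  expect_equal(tw$state, "NY")
  expect_equal(tw$surname, "Chen")
  expect_equal(tw$polarity, "positive")
  expect_equal(nrow(parse_errors(tw)), 0L)
})

test_that("empty inputs yield empty corpora", {
  jl <- write_jsonl_corpus(character(0))
  expect_equal(nrow(read_tweets(jl)), 0L)
  csvp <- tempfile(fileext = ".csv")
  writeLines("message_id,tweet_date,tweet_text", csvp)
  expect_equal(nrow(read_tweets(csvp)), 0L)
})

test_that("malformed dates are collected with line numbers, never dropped silently", {
  path <- write_jsonl_corpus(c(
    '{"message_id":"a","tweet_date":"2020-10-01","tweet_text":"ok"}',
    '{"message_id":"b","tweet_date":"2020-13-45","tweet_text":"bad date"}',
    '{"message_id":"c","tweet_date":"2020-10-02","tweet_text":"ok"}'))
  tw <- read_tweets(path)
  err <- parse_errors(tw)
  expect_equal(nrow(tw), 2L)
  expect_equal(nrow(err), 1L)
  expect_equal(attr(tw, "n_skipped"), 1L)
  expect_equal(err$line, 2L)
  expect_match(err$message, "2020-13-45")
  # conservation: rows in = rows parsed + rows reported
  expect_equal(3L, nrow(tw) + nrow(err))
})

test_that("absent surnames are NA, not empty strings, and missing mandatory columns are fatal", {
  path <- write_jsonl_corpus(
    '{"message_id":"a","tweet_date":"2020-10-01","tweet_text":"ok","surname":""}')
  tw <- read_tweets(path)
  expect_true(is.na(tw$surname))
  csvp <- tempfile(fileext = ".csv")
  writeLines(c("message_id,tweet_text", "a,hello"), csvp)
  expect_error(read_tweets(csvp), "tweet_date")
})

test_that("parse-error accounting holds on a messy mixed file", {
  good <- sprintf(
    '{"message_id":"g%d","tweet_date":"2020-10-%02d","tweet_text":"x"}',
    1:5, 1:5)
  bad <- c('not json at all',
           '{"message_id":"g1","tweet_date":"2020-10-09","tweet_text":"dup"}',
           '{"tweet_date":"2020-10-10","tweet_text":"no id"}',
           '{"message_id":"z","tweet_date":"junk","tweet_text":"x"}')
  tw <- read_tweets(write_jsonl_corpus(sample(c(good, bad))))
  expect_equal(nrow(tw) + nrow(parse_errors(tw)), 9L)
  expect_equal(nrow(tw), 5L)
})

test_that("surname table rows renormalize to exactly 100", {
  tab <- example_surname_table()
  w <- tab[tab$surname == "WASHINGTON", ]
  expect_equal(w$black, 87.53, tolerance = 1e-12)
  sums <- rowSums(tab[, c("white", "black", "api", "aian", "two_prace",
                          "hispanic")])
  expect_equal(sums, rep(100, nrow(tab)), tolerance = 1e-12)
})

test_that("surname rows off 100 beyond tolerance are rejected, near-100 rows rescaled", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("name,white,black,api,aian,two_prace,hispanic",
               "Allzero,0,0,0,0,0,0",
               "Near,50,49.8,0,0,0,0",
               "Dup,100,0,0,0,0,0",
               "Dup,0,100,0,0,0,0"), path)
  expect_warning(expect_warning(tab <- read_surname_table(path),
                                "ALLZERO"), "DUP")
  expect_false("ALLZERO" %in% tab$surname)
  near <- tab[tab$surname == "NEAR", ]
  expect_equal(near$white + near$black, 100, tolerance = 1e-12)
  expect_equal(near$white, 50 * 100 / 99.8, tolerance = 1e-12)
  # duplicate: last row wins
  expect_equal(tab$black[tab$surname == "DUP"], 100)
  # the packaged table drops the suppressed-cell row the same way
  expect_warning(read_surname_table(op_example("surname_race_table.csv")),
                 "Beyale", ignore.case = TRUE)
})

test_that("score tables round-trip: exact strings/integers, reals to 12 significant digits", {
  df <- data.frame(date = as.Date("2020-10-01") + 0:2,
                   stratum = c("CA", "NY", "TX"), n = c(1L, 0L, 7L),
                   pes = c(0.1234567890123, 1e-9, 42))
  path <- tempfile(fileext = ".csv")
  write_daily_scores(df, path)
  back <- read_daily_scores(path)
  expect_equal(back$stratum, df$stratum)
  expect_equal(back$n, df$n)
  expect_equal(back$date, df$date)
  expect_equal(back$pes, df$pes, tolerance = 1e-11)

  # empty table -> header only
  write_daily_scores(df[0, ], path)
  expect_equal(length(readLines(path)), 1L)

  # property: 1000 random rows under the stated precision contract
  set.seed(42)
  big <- data.frame(
    stratum = sample(LETTERS, 1000, TRUE),
    n = sample.int(1e6, 1000),
    value = runif(1000) * 10^sample(-8:8, 1000, TRUE))
  write_daily_scores(big, path)
  back <- read_daily_scores(path)
  expect_equal(back$stratum, big$stratum)
  expect_equal(back$n, big$n)
  expect_true(all(abs(back$value - big$value) <= 1e-11 * abs(big$value)))
  # and two writes are byte-identical
  p2 <- tempfile(fileext = ".csv")
  write_daily_scores(big, p2)
  expect_identical(readLines(path), readLines(p2))
})

test_that("daily series reader enforces order and non-negativity", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("date,value", "2020-10-01,5", "2020-10-03,0"), path)
  s <- read_daily_series(path)
  expect_equal(s$value, c(5, 0))
  writeLines(c("date,value", "2020-10-03,5", "2020-10-01,1"), path)
  expect_error(read_daily_series(path), "increasing")
  writeLines(c("date,value", "2020-10-01,-2"), path)
  expect_error(read_daily_series(path), "non-negative")
})

test_that("written JSONL corpora read back identically", {
  tw <- make_tweets(5, surname = c("Chen", NA, "Smith", NA, "Lee"),
                    polarity = c("positive", "neutral", "negative",
                                 "neutral", "positive"))
  path <- tempfile(fileext = ".jsonl")
  write_tweets_jsonl(tw, path)
  back <- read_tweets(path)
  expect_equal(back, tw, ignore_attr = TRUE)
})
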