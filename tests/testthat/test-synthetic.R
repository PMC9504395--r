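two_region_config <- function(days = 200, base_rate = 50, seed = 11, ...) {
  synth_config(start = "2020-10-01",
               end = format(as.Date("2020-10-01") + days - 1),
               regions = c(A = 1e6, B = 2e6),
               base_rate = base_rate, pop_ref = 1e6,
               event_days = data.frame(date = as.Date(character(0)),
                                       multiplier = numeric(0)),
               theta_schedule = NULL, seed = seed, ...)
}

test_that("zero base rate yields an empty corpus with intact schema", {
  g <- generate_corpus(two_region_config(days = 10, base_rate = 0))
  expect_equal(nrow(g$tweets), 0L)
  expect_true(all(c("message_id", "tweet_date", "tweet_text", "state",
                    "surname", "polarity") %in% names(g$tweets)))
})

test_that("mean daily volumes follow the population power law", {
  cfg <- two_region_config(days = 200, base_rate = 50)
  g <- generate_corpus(cfg)
  nA <- sum(g$tweets$state == "A") / 200
  nB <- sum(g$tweets$state == "B") / 200
  # E[N_B]/E[N_A] = 2^beta; each daily count is Poisson, so over 200 days
  # se of the per-region mean is sqrt(lambda/200)
  lamA <- 50
  lamB <- 50 * 2^0.725
  expect_lt(abs(nA - lamA), 3 * sqrt(lamA / 200))
  expect_lt(abs(nB - lamB), 3 * sqrt(lamB / 200))
  expect_lt(abs(nB / nA - 2^0.725), 0.1)
})

test_that("event-day multipliers scale the expected counts", {
  cfg <- synth_config(start = "2020-10-01", end = "2020-10-10",
                      regions = c(A = 1e6), base_rate = 100, pop_ref = 1e6,
                      event_days = data.frame(
                        date = as.Date("2020-10-05"), multiplier = 3),
                      seed = 2)
  ec <- generate_corpus(cfg)$truth$expected_counts
  expect_equal(ec$lambda[ec$date == as.Date("2020-10-05")], 300)
  expect_equal(ec$lambda[ec$date == as.Date("2020-10-04")], 100)
})

test_that("degenerate polarity schedules are honoured exactly", {
  days <- seq(as.Date("2020-10-01"), as.Date("2020-10-05"), by = "day")
  sched <- data.frame(date = days, positive = 1, neutral = 0, negative = 0)
  cfg <- synth_config(start = "2020-10-01", end = "2020-10-05",
                      regions = c(A = 1e6), base_rate = 200,
                      theta_schedule = sched, seed = 3)
  g <- generate_corpus(cfg)
  expect_gt(nrow(g$tweets), 0)
  expect_true(all(g$tweets$polarity == "positive"))
})

test_that("identical config and seed reproduce the corpus exactly", {
  cfg <- two_region_config(days = 20, seed = 99)
  g1 <- generate_corpus(cfg)
  g2 <- generate_corpus(cfg)
  expect_identical(g1$tweets, g2$tweets)
  expect_identical(g1$truth$topics, g2$truth$topics)
})

test_that("empirical polarity proportions converge to the schedule", {
  days <- seq(as.Date("2020-10-01"), as.Date("2020-10-03"), by = "day")
  theta <- c(0.5, 0.3, 0.2)
  sched <- data.frame(date = days, positive = theta[1], neutral = theta[2],
                      negative = theta[3])
  cfg <- synth_config(start = "2020-10-01", end = "2020-10-03",
                      regions = c(A = 1e6), base_rate = 12000,
                      theta_schedule = sched, seed = 5)
  g <- generate_corpus(cfg)
  for (d in split(g$tweets, g$tweets$tweet_date)) {
    n <- nrow(d)
    expect_gt(n, 10000)
    emp <- c(mean(d$polarity == "positive"), mean(d$polarity == "neutral"),
             mean(d$polarity == "negative"))
    expect_true(all(abs(emp - theta) < 3 * sqrt(theta * (1 - theta) / n)))
  }
})

test_that("surname frequencies match the pool weights (chi-square GOF)", {
  cfg <- synth_config(start = "2020-10-01", end = "2020-10-05",
                      regions = c(A = 1e6), base_rate = 10000, seed = 8)
  g <- generate_corpus(cfg)
  n <- nrow(g$tweets)
  expect_gt(n, 50000)
  pool <- default_surname_pool()
  obs <- table(factor(ifelse(is.na(g$tweets$surname), "",
                             g$tweets$surname), levels = pool$surname))
  gof <- chisq.test(as.numeric(obs), p = pool$weight / sum(pool$weight))
  expect_gt(gof$p.value, 0.001)
})

test_that("post templates contain no lexicon keyword", {
  # precision of topic tagging is exactly testable only because the
  # un-injected template text never fires the lexicon
  lex <- default_lexicon()
  for (tpl in opinionpulse:::SYNTH_TEMPLATES) {
    expect_length(tag_topics(tpl, lex), 0)
  }
})

test_that("separable labelled corpora are learned perfectly, exchangeable ones at chance", {
  sep <- generate_labeled_sentiment_corpus(60, vocab_separation = 1, seed = 4)
  m <- train_nb(sep$text, sep$polarity)
  acc <- mean(classify_all(m, sep$text)$polarity == sep$polarity)
  expect_equal(acc, 1.0)

  mix <- generate_labeled_sentiment_corpus(400, vocab_separation = 0, seed = 4)
  m2 <- train_nb(mix$text, mix$polarity)
  acc2 <- mean(classify_all(m2, mix$text)$polarity == mix$polarity)
  # chance level 1/3 within ~4 binomial sd (n = 1200)
  expect_lt(abs(acc2 - 1 / 3), 4 * sqrt((1 / 3) * (2 / 3) / 1200) + 0.02)

  tiny <- generate_labeled_sentiment_corpus(1, vocab_separation = 1, seed = 1)
  expect_equal(nrow(tiny), 3L)
})

test_that("daily series shapes behave as configured", {
  days <- seq(as.Date("2021-01-01"), by = "day", length.out = 5)
  s <- generate_daily_series(days, "constant", level = 100)
  expect_equal(s$value, rep(100, 5))
  p <- generate_daily_series(days, "peaked", peak_date = days[3])
  expect_equal(which.max(p$value), 3L)
  r1 <- generate_daily_series(days, "peaked", noise_sd = 5, seed = 7)
  r2 <- generate_daily_series(days, "peaked", noise_sd = 5, seed = 7)
  expect_identical(r1, r2)
  expect_true(all(r1$value >= 0))
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(regions = numeric(0)), "empty region")
  expect_error(synth_config(event_days = data.frame(
    date = as.Date("2020-11-09"), multiplier = 0.5)), "multiplier")
  bad_sched <- data.frame(date = as.Date("2020-10-01"), positive = 0.6,
                          neutral = 0.6, negative = -0.2)
  expect_error(synth_config(start = "2020-10-01", end = "2020-10-01",
                            theta_schedule = bad_sched), "probability")
})
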