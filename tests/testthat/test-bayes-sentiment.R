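test_that("observed proportions and the net score follow their defining formulas", {
  expect_equal(unname(polarity_proportions(c(5, 3, 2))), c(0.5, 0.3, 0.2))
  expect_equal(unname(polarity_proportions(c(10, 0, 0))), c(1, 0, 0))
  expect_equal(unname(polarity_proportions(c(1, 1, 1))), rep(1 / 3, 3))
  expect_error(polarity_proportions(c(0, 0, 0)), "zero posts")

  expect_equal(pss_point(c(0.5, 0.3, 0.2)), 0.3)
  expect_equal(pss_point(rep(1 / 3, 3)), 0)
  expect_equal(pss_point(c(0, 0, 1)), -1)
})

test_that("the rolling prior reduces to the balanced prior without history", {
  expect_equal(unname(build_prior(NULL)), c(1, 1, 1))
  h <- data.frame(n_pos = c(50, 20), n_neu = c(11, 10), n_neg = c(4, 5))
  # weighted pseudo-counts: base + (1/7) * (70, 21, 9)
  expect_equal(unname(build_prior(h)), c(11, 4, 16 / 7), tolerance = 1e-12)
  expect_equal(unname(build_prior(h, prior_weight = 0)), c(1, 1, 1))
  expect_error(build_prior(data.frame(n_pos = -1, n_neu = 0, n_neg = 0)),
               "negative")
})

test_that("the conjugate update adds counts to pseudo-counts", {
  expect_equal(unname(posterior_update(c(1, 1, 1), c(5, 3, 2))), c(6, 4, 3))
  expect_equal(unname(posterior_update(c(1, 1, 1), c(0, 0, 0))), c(1, 1, 1))
  post <- posterior_update(c(1, 1, 1), c(5, 3, 2))
  expect_equal(unname(post / sum(post))[1L], 6 / 13)  # Dirichlet mean
  expect_equal(sum(post / sum(post)), 1, tolerance = 1e-12)
})

test_that("credible intervals are symmetric for symmetric posteriors and tight for peaked ones", {
  ci <- pss_credible_interval(c(40, 40, 40), n_mc = 20000, seed = 1)
  expect_equal(ci$pss, 0)
  expect_lt(abs(ci$ci_low + ci$ci_high), 3 / sqrt(20000))

  peak <- pss_credible_interval(c(1001, 1, 1), n_mc = 20000, seed = 2)
  expect_equal(peak$pss, 1000 / 1003)
  expect_gt(peak$ci_low, 0.98)
  expect_true(peak$ci_high <= 1)
})

test_that("interval width shrinks as the posterior concentrates", {
  mean_prop <- c(0.5, 0.3, 0.2)
  wide <- pss_credible_interval(30 * mean_prop, n_mc = 20000, seed = 3)
  narrow <- pss_credible_interval(3000 * mean_prop, n_mc = 20000, seed = 3)
  expect_lt(narrow$ci_high - narrow$ci_low, wide$ci_high - wide$ci_low)
})

test_that("the daily series composes prior, update and interval", {
  one <- data.frame(date = as.Date("2020-10-01"), stratum = "nation",
                    n_pos = 5, n_neu = 3, n_neg = 2)
  s <- daily_pss_series(one, n_mc = 2000, seed = 1)
  expect_equal(s$pss, 3 / 13)  # posterior (6, 4, 3)
  expect_false(s$prior_only)

  # constant counts: priors stabilise after the first window, the point
  # estimate is exactly constant afterwards and near the empirical PSS
  const <- data.frame(date = as.Date("2020-10-01") + 0:29,
                      stratum = "nation", n_pos = 50, n_neu = 30, n_neg = 20)
  sc <- daily_pss_series(const, n_mc = 2000, seed = 1)
  expect_equal(length(unique(sc$pss[8:30])), 1L)
  expect_lt(abs(sc$pss[30] - 0.3), 0.01)

  # an all-silent stratum: every day flagged, score 0 from the balanced prior
  silent <- data.frame(date = as.Date("2020-10-01") + 0:4,
                       stratum = "nation", n_pos = 0, n_neu = 0, n_neg = 0)
  ss <- daily_pss_series(silent, n_mc = 2000, seed = 1)
  expect_true(all(ss$prior_only))
  expect_equal(ss$pss, rep(0, 5))
})

test_that("estimates converge to the empirical score as daily volume grows", {
  # large-sample agreement under the balanced prior
  big <- data.frame(date = as.Date("2020-10-01"), stratum = "x",
                    n_pos = 52000, n_neu = 28000, n_neg = 20000)
  s <- daily_pss_series(big, n_mc = 2000, seed = 2)
  expect_lt(abs(s$pss - 0.32), 1e-3)

  # prior influence decays: fixed history, growing day volume
  hist_counts <- matrix(c(10, 80, 10), 1)  # strongly negative-leaning prior
  for (N in c(100, 10000)) {
    prior <- build_prior(hist_counts)
    post <- posterior_update(prior, N * c(0.6, 0.2, 0.2))
    est <- (post[1] - post[3]) / sum(post)
    if (N == 100) gap_small_n <- abs(est - 0.4)
    if (N == 10000) expect_lt(abs(est - 0.4), gap_small_n)
  }
})

test_that("weekly averaging uses 7-day blocks anchored at the series start", {
  s <- data.frame(date = as.Date("2021-01-01") + 0:6, stratum = "n",
                  pss = seq(0.1, 0.7, by = 0.1))
  w <- weekly_average(s)
  expect_equal(nrow(w), 1L)
  expect_equal(w$pss, 0.4)
  expect_equal(w$week_start, as.Date("2021-01-01"))

  s8 <- rbind(s, data.frame(date = as.Date("2021-01-08"), stratum = "n",
                            pss = 0.9))
  w8 <- weekly_average(s8)
  expect_equal(nrow(w8), 2L)
  expect_equal(w8$n_days, c(7L, 1L))
  expect_equal(w8$pss[2L], 0.9)

  # a gap spanning a whole block: the empty block is omitted, not zero
  gap <- data.frame(date = as.Date("2021-01-01") + c(0:3, 15:17),
                    stratum = "n", pss = 0.5)
  wg <- weekly_average(gap)
  expect_equal(nrow(wg), 2L)
  expect_equal(wg$week_start, as.Date("2021-01-01") + c(0, 14))
})

test_that("coverage: intervals contain the generating net score at the nominal rate", {
  set.seed(99)
  n_days <- 200
  days <- as.Date("2020-10-01") + seq_len(n_days) - 1
  # slowly drifting truth
  th1 <- 0.45 + 0.10 * sin(seq_len(n_days) / 40)
  th3 <- 0.25 - 0.05 * sin(seq_len(n_days) / 40)
  th2 <- 1 - th1 - th3
  counts <- t(vapply(seq_len(n_days), function(i) {
    as.numeric(rmultinom(1, 200, c(th1[i], th2[i], th3[i])))
  }, numeric(3)))
  df <- data.frame(date = days, stratum = "nation", n_pos = counts[, 1],
                   n_neu = counts[, 2], n_neg = counts[, 3])
  s <- daily_pss_series(df, n_mc = 20000, seed = 123)
  truth <- th1 - th3
  covered <- mean(s$ci_low <= truth & truth <= s$ci_high)
  expect_gte(covered, 0.91)
  expect_lte(covered, 0.99)
})
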