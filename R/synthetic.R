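# Synthetic geo-corpus generator with known ground truth. Every
# downstream stage (engagement scoring, Bayesian sentiment, topic tagging,
# race imputation) is validated against what this generator injected.
#
# The generator emulates the structure of the real study corpus: daily
# per-state volumes that are Poisson around a power-law mean
# base_rate * (pop / pop_ref)^beta * event multiplier, with spikes on
# vaccine milestone days; three-class polarity proportions drifting over
# the study window (jumping up at the efficacy announcement); topic
# keywords injected independently per aspect into otherwise keyword-free
# template text; and surnames drawn from a pool so the race composition
# is known by construction.

# neutral post templates; deliberately free of every default lexicon
# keyword so topic-tagging precision is exactly testable
SYNTH_TEMPLATES <- c(
  "thinking a lot these days and waiting for better news",
  "went by the clinic downtown and the crowd seemed bigger than usual",
  "my family keeps asking when we can sign up around here",
  "the rollout in our county seems slower than expected honestly",
  "hoping things get back to normal sometime soon",
  "the latest numbers for our state look somewhat encouraging",
  "still reading everything before making any plans this month",
  "neighbors were talking about appointments again this morning"
)

#' Populations of the 48 contiguous states plus DC (2010 census)
#'
#' @return Named numeric vector of resident populations.
#' @export
default_state_populations <- function() {
  pop <- read_population_table(op_example("state_population_2010.csv"))
  pop[setdiff(names(pop), "nation")]
}

#' Default event-day volume multipliers
#'
#' Spikes on the study's vaccine milestone days (efficacy announcement,
#' first dose, early-March reopening news, 100-million-doses mark,
#' one-brand pause in April).
#'
#' @return Data frame `date`, `multiplier` (all >= 1).
#' @export
default_event_days <- function() {
  data.frame(
    date = as.Date(c("2020-11-09", "2020-12-14", "2021-03-02",
                     "2021-03-12", "2021-04-13")),
    multiplier = c(3, 2.5, 2, 2.5, 2)
  )
}

#' Default drifting polarity schedule
#'
#' Piecewise-linear daily (positive, neutral, negative) proportions over
#' the study window: modestly positive and volatile before the efficacy
#' announcement, a jump up on 2020-11-09, a decline into late December,
#' recovery through early 2021 and a mid-April dip.
#'
#' @param dates `Date` vector of study days.
#' @return Data frame `date`, `positive`, `neutral`, `negative`; each row
#'   sums to 1.
#' @export
default_theta_schedule <- function(dates) {
  anchors <- data.frame(
    date = as.Date(c("2020-10-01", "2020-11-08", "2020-11-09", "2020-12-28",
                     "2021-04-10", "2021-04-20", "2021-05-21")),
    positive = c(0.32, 0.34, 0.52, 0.40, 0.55, 0.47, 0.50),
    neutral  = c(0.43, 0.42, 0.33, 0.38, 0.30, 0.33, 0.32),
    negative = c(0.25, 0.24, 0.15, 0.22, 0.15, 0.20, 0.18)
  )
  x <- as.numeric(dates)
  interp <- function(col) {
    stats::approx(as.numeric(anchors$date), anchors[[col]], xout = x,
                  rule = 2)$y
  }
  th <- cbind(interp("positive"), interp("neutral"), interp("negative"))
  th <- th / rowSums(th)
  data.frame(date = dates, positive = th[, 1L], neutral = th[, 2L],
             negative = th[, 3L])
}

#' Default surname pool
#'
#' Sampling weights over the packaged census-style example surnames, plus
#' an unlisted surname and a share of posts with no surname at all (empty
#' string), so the matched fraction is realistically around one half.
#'
#' @return Data frame `surname`, `weight`.
#' @export
default_surname_pool <- function() {
  data.frame(
    surname = c("Smith", "Washington", "Chen", "Ceballos", "Kanekoa",
                "Beyale", "Garcia", ""),
    weight = c(0.24, 0.10, 0.10, 0.14, 0.04, 0.04, 0.09, 0.25),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic-study configuration
#'
#' Bundles and validates every knob of the corpus generator. The defaults
#' are the study conditions: the 2020-10-01..2021-05-21 window, the 48
#' contiguous states plus DC with 2010 populations, volume exponent
#' 0.725, a national expected volume of roughly 650-700 posts/day,
#' milestone-day spikes, the drifting polarity schedule, per-aspect
#' keyword injection, and the example surname pool.
#'
#' @param start,end Study window (ISO dates).
#' @param regions Named numeric vector of region populations (non-empty).
#' @param beta_true Volume-population exponent in (0, 1].
#' @param base_rate Expected posts/day for a region of population
#'   `pop_ref` on a non-event day.
#' @param pop_ref Reference population for `base_rate`.
#' @param event_days Data frame `date`, `multiplier` (>= 1).
#' @param theta_schedule Data frame `date`, `positive`, `neutral`,
#'   `negative` (rows sum to 1 within 1e-12); default
#'   [default_theta_schedule()] over the window.
#' @param topic_injection Named probabilities in `[0, 1]` of injecting one
#'   keyword of each topic into a post.
#' @param surname_pool Data frame `surname`, `weight` (weights >= 0 with
#'   positive sum; empty surname means an absent one).
#' @param lexicon Topic lexicon used for keyword injection.
#' @param seed Integer seed.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(start = "2020-10-01", end = "2021-05-21",
                         regions = default_state_populations(),
                         beta_true = 0.725, base_rate = 4.5, pop_ref = 1e6,
                         event_days = default_event_days(),
                         theta_schedule = NULL,
                         topic_injection = c(vaccine_type = 0.15,
                                             phased_vaccination = 0.20,
                                             health_concern = 0.15),
                         surname_pool = default_surname_pool(),
                         lexicon = default_lexicon(),
                         seed = 1) {
  dates <- seq(as.Date(start), as.Date(end), by = "day")
  if (!length(regions)) stop("empty region list", call. = FALSE)
  if (is.null(names(regions)) || any(!nzchar(names(regions)))) {
    stop("regions must be a named vector of populations", call. = FALSE)
  }
  stopifnot(all(regions > 0), beta_true > 0, base_rate >= 0, pop_ref > 0)
  if (is.null(theta_schedule)) theta_schedule <- default_theta_schedule(dates)
  th <- as.matrix(theta_schedule[, c("positive", "neutral", "negative")])
  if (any(abs(rowSums(th) - 1) > 1e-12) || any(th < 0)) {
    stop("theta_schedule rows must be probability vectors summing to 1",
         call. = FALSE)
  }
  if (!all(dates %in% theta_schedule$date)) {
    stop("theta_schedule must cover every study day", call. = FALSE)
  }
  if (nrow(event_days) && any(event_days$multiplier < 1)) {
    stop("event multipliers must be >= 1", call. = FALSE)
  }
  if (any(surname_pool$weight < 0) || sum(surname_pool$weight) <= 0) {
    stop("surname weights must be >= 0 with a positive sum", call. = FALSE)
  }
  stopifnot(all(topic_injection >= 0), all(topic_injection <= 1))
  structure(
    list(dates = dates, regions = regions, beta_true = beta_true,
         base_rate = base_rate, pop_ref = pop_ref, event_days = event_days,
         theta_schedule = theta_schedule, topic_injection = topic_injection,
         surname_pool = surname_pool, lexicon = lexicon,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# expected count for region r on day d:
# base_rate * (pop_r / pop_ref)^beta_true * multiplier(d)
expected_counts <- function(config) {
  mult <- rep(1, length(config$dates))
  if (nrow(config$event_days)) {
    hit <- match(config$event_days$date, config$dates)
    mult[hit[!is.na(hit)]] <- config$event_days$multiplier[!is.na(hit)]
  }
  rate_r <- config$base_rate *
    (config$regions / config$pop_ref)^config$beta_true
  data.frame(
    date = rep(config$dates, each = length(config$regions)),
    region = rep(names(config$regions), times = length(config$dates)),
    lambda = as.numeric(outer(rate_r, mult))  # region-major within day
  )
}

#' Generate a synthetic geo-corpus with ground truth
#'
#' Draws per-region daily post counts from a Poisson around the power-law
#' mean, polarities from the day's schedule, topic keywords independently
#' per aspect (appended to a keyword-free template), and surnames from the
#' pool. Fully reproducible given the config seed; all randomness flows
#' from a single `set.seed` at entry in a fixed draw order.
#'
#' @param config A `synth_config`.
#' @return List with `tweets` (a [read_tweets()]-shaped data frame, with
#'   polarity labels filled in) and `truth` (list: `expected_counts` with
#'   the per-day per-region Poisson means, `theta` schedule,
#'   `topics` logical matrix of injected aspects per post, `config`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  ec <- expected_counts(config)
  n_cell <- rpois(nrow(ec), ec$lambda)
  n <- sum(n_cell)
  tweets <- data.frame(
    message_id = sprintf("t%08d", seq_len(n)),
    tweet_date = rep(ec$date, n_cell),
    tweet_text = character(n),
    state = rep(ec$region, n_cell),
    surname = character(n),
    polarity = character(n),
    stringsAsFactors = FALSE
  )
  truth_topics <- matrix(FALSE, nrow = n, ncol = length(TOPIC_NAMES),
                         dimnames = list(NULL, TOPIC_NAMES))
  if (n > 0) {
    # polarity, day by day in date order
    th <- config$theta_schedule
    for (d in split(seq_len(n), as.integer(tweets$tweet_date))) {
      day <- tweets$tweet_date[d[1L]]
      p <- as.numeric(th[match(day, th$date),
                         c("positive", "neutral", "negative")])
      tweets$polarity[d] <- sample(POLARITY_LEVELS, length(d),
                                   replace = TRUE, prob = p)
    }
    # template text plus independently injected topic keywords
    text <- sample(SYNTH_TEMPLATES, n, replace = TRUE)
    for (topic in TOPIC_NAMES) {
      p_inj <- config$topic_injection[[topic]]
      if (is.null(p_inj) || p_inj <= 0) next
      inj <- runif(n) < p_inj
      if (any(inj)) {
        kw <- sample(config$lexicon[[topic]], sum(inj), replace = TRUE)
        text[inj] <- paste(text[inj], kw)
        truth_topics[inj, topic] <- TRUE
      }
    }
    tweets$tweet_text <- text
    surname <- sample(config$surname_pool$surname, n, replace = TRUE,
                      prob = config$surname_pool$weight)
    tweets$surname <- ifelse(nzchar(surname), surname, NA_character_)
  }
  list(
    tweets = tweets,
    truth = list(expected_counts = ec, theta = config$theta_schedule,
                 topics = truth_topics, config = config)
  )
}

# class-specific and shared vocabularies for the labelled sentiment corpus
SENTIMENT_VOCAB <- list(
  positive = c("great", "happy", "relieved", "grateful", "hopeful", "glad",
               "excited", "thankful"),
  neutral = c("update", "schedule", "report", "notice", "today", "weekly",
              "county", "listed"),
  negative = c("awful", "angry", "scared", "worried", "upset", "terrible",
               "anxious", "doubtful"),
  shared = c("vaccine", "shot", "clinic", "people", "time", "day", "news",
             "state")
)

#' Generate a labelled sentiment training corpus
#'
#' Emits `n_per_class` documents per polarity class over class-specific
#' and shared vocabularies. Each token comes from the class vocabulary
#' with probability `vocab_separation`, else from the shared one:
#' separation 1 gives disjoint (perfectly separable) vocabularies,
#' separation 0 gives identical class distributions (chance-level
#' classification).
#'
#' @param n_per_class Documents per class (>= 1).
#' @param vocab_separation Real in `[0, 1]`.
#' @param seed Integer seed.
#' @param doc_length Tokens per document.
#' @return Data frame `text`, `polarity` with `3 * n_per_class` rows.
#' @export
generate_labeled_sentiment_corpus <- function(n_per_class,
                                              vocab_separation = 1,
                                              seed = 1, doc_length = 8) {
  stopifnot(n_per_class >= 1, vocab_separation >= 0, vocab_separation <= 1)
  set.seed(seed)
  rows <- lapply(POLARITY_LEVELS, function(cl) {
    texts <- vapply(seq_len(n_per_class), function(i) {
      own <- runif(doc_length) < vocab_separation
      toks <- ifelse(own,
                     sample(SENTIMENT_VOCAB[[cl]], doc_length, replace = TRUE),
                     sample(SENTIMENT_VOCAB$shared, doc_length, replace = TRUE))
      paste(toks, collapse = " ")
    }, character(1))
    data.frame(text = texts, polarity = cl, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a daily value series
#'
#' Stand-in for externally supplied daily case or vaccination counts:
#' either a constant level or a single Gaussian-shaped peak at a
#' configurable date, with optional non-negative noise.
#'
#' @param dates Non-empty `Date` vector.
#' @param shape `"constant"` or `"peaked"`.
#' @param level Baseline value.
#' @param peak_date Date of the maximum (default: middle of the range).
#' @param peak_height Height of the peak above baseline (default
#'   `9 * level`).
#' @param width Peak standard deviation in days.
#' @param noise_sd Standard deviation of additive noise (values are
#'   clamped at 0); 0 for a deterministic series.
#' @param seed Optional integer seed.
#' @return Data frame `date`, `value` (all values >= 0).
#' @export
generate_daily_series <- function(dates, shape = c("constant", "peaked"),
                                  level = 100, peak_date = NULL,
                                  peak_height = NULL, width = 7,
                                  noise_sd = 0, seed = NULL) {
  shape <- match.arg(shape)
  stopifnot(length(dates) >= 1)
  dates <- as.Date(dates)
  if (!is.null(seed)) set.seed(seed)
  v <- rep(as.numeric(level), length(dates))
  if (shape == "peaked") {
    if (is.null(peak_date)) peak_date <- dates[ceiling(length(dates) / 2)]
    if (is.null(peak_height)) peak_height <- 9 * level
    z <- as.numeric(dates - as.Date(peak_date)) / width
    v <- v + peak_height * exp(-0.5 * z^2)
  }
  if (noise_sd > 0) v <- v + stats::rnorm(length(dates), 0, noise_sd)
  data.frame(date = dates, value = pmax(v, 0))
}
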