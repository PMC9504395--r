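# Dirichlet-multinomial model of daily three-class sentiment proportions.
# The net sentiment score (PSS) is theta_positive - theta_negative; its
# daily posterior uses an informative prior built from the preceding
# week's polarity counts, falling back to the balanced non-informative
# prior when no history exists.

#' Daily polarity counts per stratum
#'
#' Aggregates labelled tweets into per-(date, stratum) counts of positive,
#' neutral and negative posts — the sufficient statistics for the sentiment
#' model. The grid is dense over `dates` (default: corpus date range), so
#' days with no posts appear with all-zero counts.
#'
#' @param tweets Tweet data frame with a non-`NA` `polarity` column.
#' @param stratify_by One of `nation`, `state`, `race`, `topic`.
#' @param dates Optional `Date` vector for the dense grid.
#' @return Data frame `date`, `stratum`, `n_pos`, `n_neu`, `n_neg`, `N`,
#'   sorted by stratum then date.
#' @export
count_polarities <- function(tweets, stratify_by = c("nation", "state",
                             "race", "topic"), dates = NULL) {
  stratify_by <- match.arg(stratify_by)
  if (anyNA(tweets$polarity)) {
    stop("all tweets must carry a polarity label before counting",
         call. = FALSE)
  }
  lab <- stratum_labels(tweets, stratify_by)
  if (is.null(dates)) {
    if (!nrow(tweets)) stop("empty corpus and no dates given", call. = FALSE)
    rng <- range(tweets$tweet_date)
    dates <- seq(rng[1], rng[2], by = "day")
  }
  strata <- sort(unique(lab$label))
  day <- as.character(tweets$tweet_date[lab$idx])
  pol <- factor(tweets$polarity[lab$idx], levels = POLARITY_LEVELS)
  grid <- expand.grid(date = as.character(dates), stratum = strata,
                      stringsAsFactors = FALSE)
  key_grid <- paste(grid$date, grid$stratum, sep = "\r")
  out <- grid
  for (k in seq_along(POLARITY_LEVELS)) {
    sel <- pol == POLARITY_LEVELS[k]
    tab <- table(key = paste(day[sel], lab$label[sel], sep = "\r"))
    hit <- match(key_grid, names(tab))
    out[[c("n_pos", "n_neu", "n_neg")[k]]] <-
      ifelse(is.na(hit), 0L, as.integer(tab[hit]))
  }
  out$N <- out$n_pos + out$n_neu + out$n_neg
  out$date <- as.Date(out$date)
  out <- out[order(out$stratum, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Observed polarity proportions
#'
#' `theta_i = n_i / N` for the three polarities.
#'
#' @param counts Numeric 3-vector `(n_pos, n_neu, n_neg)` of non-negative
#'   counts with a positive total.
#' @return Named 3-vector `(positive, neutral, negative)` summing to 1.
#' @export
polarity_proportions <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3L, all(counts >= 0))
  if (sum(counts) == 0) {
    stop("proportions undefined for a day with zero posts", call. = FALSE)
  }
  setNames(counts / sum(counts), POLARITY_LEVELS)
}

#' Net sentiment point score
#'
#' `PSS = theta_positive - theta_negative`, in `[-1, 1]`.
#'
#' @param theta Polarity proportion 3-vector.
#' @return A number in `[-1, 1]`.
#' @export
pss_point <- function(theta) {
  theta <- as.numeric(theta)
  stopifnot(length(theta) == 3L)
  theta[1L] - theta[3L]
}

#' Build the rolling informative prior
#'
#' Dirichlet pseudo-counts `alpha_i = base + prior_weight * sum(history
#' n_i)` over the preceding window. With no history this reduces to the
#' balanced non-informative prior `(base, base, base)`. The default weight
#' `1/7` makes a full week of history worth about one average day of data.
#'
#' @param history Data frame (columns `n_pos`, `n_neu`, `n_neg`) or numeric
#'   matrix of counts for the days in the preceding window; may have zero
#'   rows.
#' @param prior_weight Non-negative weight applied to the summed history.
#' @param base Positive baseline pseudo-count.
#' @return Named positive 3-vector of Dirichlet parameters.
#' @export
build_prior <- function(history = NULL, prior_weight = 1 / 7, base = 1) {
  stopifnot(base > 0, prior_weight >= 0)
  tot <- c(0, 0, 0)
  if (!is.null(history) && NROW(history)) {
    h <- if (is.data.frame(history)) {
      as.matrix(history[, c("n_pos", "n_neu", "n_neg")])
    } else {
      matrix(history, ncol = 3L)
    }
    if (any(h < 0)) stop("negative counts in history", call. = FALSE)
    tot <- colSums(h)
  }
  setNames(base + prior_weight * tot, POLARITY_LEVELS)
}

#' Conjugate posterior update
#'
#' Dirichlet prior plus multinomial counts: `alpha_i' = alpha_i + n_i`.
#'
#' @param prior Positive 3-vector of Dirichlet parameters.
#' @param counts Non-negative count 3-vector `(n_pos, n_neu, n_neg)`.
#' @return Named 3-vector of posterior Dirichlet parameters.
#' @export
posterior_update <- function(prior, counts) {
  prior <- as.numeric(prior)
  counts <- as.numeric(counts)
  stopifnot(length(prior) == 3L, length(counts) == 3L,
            all(prior > 0), all(counts >= 0))
  setNames(prior + counts, POLARITY_LEVELS)
}

# one matrix of Dirichlet(alpha) draws; theta rows sum to 1
rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

#' Credible interval for the net sentiment score
#'
#' Draws `n_mc` samples from the Dirichlet posterior, forms
#' `theta_1 - theta_3` per draw, and returns equal-tailed empirical
#' quantiles. The point estimate is the closed-form posterior mean
#' `(alpha_1 - alpha_3) / sum(alpha)` (deterministic, not the Monte-Carlo
#' mean).
#'
#' @param post Positive 3-vector of posterior Dirichlet parameters.
#' @param level Credibility level in (0, 1).
#' @param n_mc Number of Monte-Carlo draws (>= 1000).
#' @param seed Optional integer seed (sets the RNG before drawing).
#' @return One-row data frame `pss`, `ci_low`, `ci_high`, `level`, `n_mc`.
#' @export
pss_credible_interval <- function(post, level = 0.95, n_mc = 20000,
                                  seed = NULL) {
  post <- as.numeric(post)
  stopifnot(length(post) == 3L, all(post > 0), level > 0, level < 1,
            n_mc >= 1000)
  if (!is.null(seed)) set.seed(seed)
  th <- rdirichlet(n_mc, post)
  s <- th[, 1L] - th[, 3L]
  q <- quantile(s, c((1 - level) / 2, 1 - (1 - level) / 2),
                names = FALSE, type = 7)
  data.frame(
    pss = (post[1L] - post[3L]) / sum(post),
    ci_low = q[1L], ci_high = q[2L], level = level, n_mc = as.integer(n_mc)
  )
}

#' Daily net-sentiment series with rolling informative priors
#'
#' For each stratum and each day, a Dirichlet prior is built from the
#' polarity counts of the preceding `window_days` days ([build_prior()]),
#' updated with that day's counts ([posterior_update()]), and summarised
#' as a point estimate with an equal-tailed credible interval
#' ([pss_credible_interval()]). Days at the start of the series with no
#' history use the balanced non-informative prior; days with zero posts
#' yield the prior-only estimate and are flagged `prior_only`.
#'
#' @param counts Output of [count_polarities()] (or any data frame with
#'   `date`, `stratum`, `n_pos`, `n_neu`, `n_neg`).
#' @param window_days Length of the trailing history window (days).
#' @param prior_weight,base Prior construction knobs, see [build_prior()].
#' @param level,n_mc Interval knobs, see [pss_credible_interval()].
#' @param seed Optional integer seed set once before the (stratum-sorted,
#'   date-sorted) sweep, making the whole series reproducible.
#' @return Data frame `date`, `stratum`, `pss`, `ci_low`, `ci_high`,
#'   `level`, `N`, `prior_only`, `n_mc`.
#' @export
daily_pss_series <- function(counts, window_days = 7, prior_weight = 1 / 7,
                             base = 1, level = 0.95, n_mc = 20000,
                             seed = NULL) {
  stopifnot(window_days >= 1)
  if (!is.null(seed)) set.seed(seed)
  counts <- counts[order(counts$stratum, counts$date), , drop = FALSE]
  cmat <- as.matrix(counts[, c("n_pos", "n_neu", "n_neg")])
  res <- vector("list", nrow(counts))
  for (stratum in unique(counts$stratum)) {
    rows <- which(counts$stratum == stratum)
    d <- counts$date[rows]
    for (j in seq_along(rows)) {
      in_window <- d >= d[j] - window_days & d < d[j]
      prior <- build_prior(cmat[rows[in_window], , drop = FALSE],
                           prior_weight = prior_weight, base = base)
      day_counts <- cmat[rows[j], ]
      post <- posterior_update(prior, day_counts)
      ci <- pss_credible_interval(post, level = level, n_mc = n_mc)
      ci$date <- d[j]
      ci$stratum <- stratum
      ci$N <- sum(day_counts)
      ci$prior_only <- sum(day_counts) == 0
      res[[rows[j]]] <- ci
    }
  }
  out <- do.call(rbind, res)
  out <- out[, c("date", "stratum", "pss", "ci_low", "ci_high", "level",
                 "N", "prior_only", "n_mc")]
  rownames(out) <- NULL
  out
}

#' Weekly averages of the daily net sentiment score
#'
#' Averages `pss` over consecutive 7-day blocks anchored at each stratum's
#' first date. Blocks with no days present are omitted rather than emitted
#' as zero.
#'
#' @param series Output of [daily_pss_series()] (needs `date`, `stratum`,
#'   `pss`).
#' @return Data frame `stratum`, `week_start`, `pss`, `n_days`.
#' @export
weekly_average <- function(series) {
  if (!nrow(series)) stop("empty series", call. = FALSE)
  res <- lapply(split(series, series$stratum), function(s) {
    block <- as.integer(s$date - min(s$date)) %/% 7L
    agg <- vapply(split(s$pss, block), mean, numeric(1))
    ndays <- vapply(split(s$pss, block), length, integer(1))
    data.frame(
      stratum = s$stratum[1L],
      week_start = min(s$date) + 7 * as.integer(names(agg)),
      pss = as.numeric(agg),
      n_days = as.integer(ndays),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out <- out[order(out$stratum, out$week_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
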