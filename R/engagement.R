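# Public engagement score: daily post volume normalised by a sublinear
# power of population, so regions of very different sizes are comparable.

#' Public engagement score
#'
#' `PES = N / pop^beta`: the number of vaccine-related posts divided by the
#' regional population raised to the scaling exponent `beta`. The exponent
#' reflects the sublinear growth of social-media volume with population
#' (empirically between 0.67 and 0.78); the default is 0.725.
#'
#' @param n Post count(s), non-negative.
#' @param pop Population size(s), >= 1.
#' @param beta Scaling exponent, > 0.
#' @return Numeric PES value(s), >= 0; exactly 0 iff `n` is 0.
#' @export
#' @examples
#' compute_pes(1000, 1e6)  # 1000 / 10^4.35
compute_pes <- function(n, pop, beta = 0.725) {
  if (any(is.na(n)) || any(n < 0)) {
    stop("post count must be non-negative", call. = FALSE)
  }
  if (any(is.na(pop)) || any(pop < 1)) {
    stop("population must be >= 1", call. = FALSE)
  }
  if (length(beta) != 1L || is.na(beta) || beta <= 0) {
    stop("beta must be a single positive number", call. = FALSE)
  }
  n / pop^beta
}

# resolve the population denominator for each stratum label; `mode`
# decides how labels map into the population table
stratum_populations <- function(strata, populations, mode) {
  national <- function() {
    if ("nation" %in% names(populations)) {
      populations[["nation"]]
    } else {
      sum(populations)
    }
  }
  if (mode %in% c("nation", "topic")) {
    # topics have no population of their own; the national total is the
    # documented denominator
    return(setNames(rep(national(), length(strata)), strata))
  }
  missing_strata <- setdiff(strata, names(populations))
  if (length(missing_strata)) {
    stop("no population entry for ", mode, " stratum/strata: ",
         paste(missing_strata, collapse = ", "), call. = FALSE)
  }
  setNames(as.numeric(populations[strata]), strata)
}

# per-(date, stratum) tweet labels under a stratification mode; topic mode
# expands multi-topic tweets into one row per tagged topic
stratum_labels <- function(tweets, stratify_by) {
  switch(stratify_by,
    nation = list(idx = seq_len(nrow(tweets)),
                  label = rep("nation", nrow(tweets))),
    state = {
      keep <- which(!is.na(tweets$state))
      list(idx = keep, label = tweets$state[keep])
    },
    race = {
      if (is.null(tweets$race)) {
        stop("race stratification needs a 'race' column ",
             "(run annotate_corpus first)", call. = FALSE)
      }
      keep <- which(!is.na(tweets$race) & tweets$race != RACE_UNKNOWN)
      list(idx = keep, label = tweets$race[keep])
    },
    topic = {
      if (is.null(tweets$topics)) {
        stop("topic stratification needs a 'topics' column ",
             "(run annotate_topics first)", call. = FALSE)
      }
      tags <- strsplit(ifelse(is.na(tweets$topics), "", tweets$topics), ";",
                       fixed = TRUE)
      len <- lengths(tags)
      list(idx = rep(seq_len(nrow(tweets)), len), label = unlist(tags))
    },
    stop("unknown stratification: ", stratify_by, call. = FALSE)
  )
}

#' Daily engagement scores per stratum
#'
#' Counts posts per calendar day within each stratum of the requested
#' stratification and converts counts to PES with [compute_pes()]. State
#' strata are normalised by state population, race strata by national race
#' population, and national and topic strata by the national total
#' population (a topic has no population of its own). Race label
#' `unknown` has no population denominator and is excluded.
#'
#' @param tweets Tweet data frame ([read_tweets()] columns; a `race` or
#'   `topics` column is required for those stratifications).
#' @param populations Named numeric vector or `region,population` data
#'   frame. Must cover every stratum; an optional `nation` entry overrides
#'   the national total (otherwise the entries are summed).
#' @param stratify_by One of `nation`, `state`, `race`, `topic`.
#' @param beta Scaling exponent passed to [compute_pes()].
#' @param dense_grid If `TRUE`, emit `n = 0` rows so every stratum covers
#'   every day of `dates` (default: the corpus date range).
#' @param dates Optional `Date` vector defining the dense grid.
#' @return Data frame `date`, `stratum`, `n`, `population`, `beta`, `pes`.
#' @export
daily_pes <- function(tweets, populations, stratify_by = c("nation", "state",
                      "race", "topic"), beta = 0.725, dense_grid = FALSE,
                      dates = NULL) {
  stratify_by <- match.arg(stratify_by)
  if (is.data.frame(populations)) {
    populations <- setNames(as.numeric(populations$population),
                            populations$region)
  }
  lab <- stratum_labels(tweets, stratify_by)
  day <- tweets$tweet_date[lab$idx]
  counts <- as.data.frame(table(date = as.character(day),
                                stratum = lab$label),
                          stringsAsFactors = FALSE)
  names(counts)[3] <- "n"
  counts <- counts[counts$n > 0, , drop = FALSE]
  if (dense_grid) {
    if (is.null(dates)) {
      rng <- range(tweets$tweet_date)
      dates <- seq(rng[1], rng[2], by = "day")
    }
    strata <- sort(unique(lab$label))
    grid <- expand.grid(date = as.character(dates), stratum = strata,
                        stringsAsFactors = FALSE)
    key <- paste(grid$date, grid$stratum, sep = "\r")
    hit <- match(key, paste(counts$date, counts$stratum, sep = "\r"))
    grid$n <- ifelse(is.na(hit), 0L, counts$n[hit])
    counts <- grid
  }
  pops <- stratum_populations(unique(counts$stratum), populations,
                              stratify_by)
  counts$population <- as.numeric(pops[counts$stratum])
  out <- data.frame(
    date = as.Date(counts$date),
    stratum = counts$stratum,
    n = as.integer(counts$n),
    population = counts$population,
    beta = beta,
    pes = compute_pes(counts$n, counts$population, beta),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$stratum, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}
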