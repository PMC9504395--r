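# Probabilistic race imputation from user surnames via a census-style
# surname race distribution table. Each post is assigned one label drawn
# with the probabilities of its surname's row; unmatched or absent
# surnames become "unknown".

#' Normalise a surname for table lookup
#'
#' Trims whitespace, strips diacritics (Unicode-to-ASCII transliteration)
#' and uppercases, matching the ASCII-uppercase census table dialect.
#'
#' @param raw Character vector of raw surnames (`NA` allowed).
#' @return Character vector; empty or `NA` input yields `""`.
#' @export
#' @examples
#' normalize_surname("Cebállos")  # "CEBALLOS"
normalize_surname <- function(raw) {
  raw[is.na(raw)] <- ""
  x <- stringi::stri_trans_general(trimws(raw), "Latin-ASCII")
  toupper(x)
}

#' Assign a race label from a surname
#'
#' Draws one label with probabilities equal to the surname's renormalised
#' row percentages, consuming exactly one uniform variate via the fixed
#' cumulative ordering white, black, api, aian, two_prace, hispanic.
#' Surnames absent from the table (or empty) yield `"unknown"`.
#'
#' @param surname Raw surname string (normalised internally).
#' @param table Surname table from [read_surname_table()].
#' @param u Uniform(0,1) variate to invert; defaults to a fresh draw.
#' @return One of `white`, `black`, `api`, `aian`, `two_prace`,
#'   `hispanic`, `unknown`.
#' @export
assign_race <- function(surname, table, u = runif(1)) {
  stopifnot(length(surname) == 1L, length(u) == 1L, u >= 0, u <= 1)
  row <- match(normalize_surname(surname), table$surname)
  if (is.na(row) || !nzchar(normalize_surname(surname))) return(RACE_UNKNOWN)
  p <- as.numeric(table[row, RACE_LEVELS]) / 100
  idx <- findInterval(u, cumsum(p), left.open = TRUE) + 1L
  RACE_LEVELS[min(idx, length(RACE_LEVELS))]
}

#' Annotate a corpus with imputed race labels
#'
#' Adds a `race` column: one independent label per post, drawn in input
#' order with one uniform variate per post (posts with unmatched surnames
#' keep their position in the draw stream, so any run is replayable). With
#' `per_surname = TRUE` all posts sharing a normalised surname receive the
#' label drawn at that surname's first appearance.
#'
#' @param tweets Tweet data frame with a `surname` column.
#' @param table Surname table from [read_surname_table()].
#' @param seed Integer seed for the draw stream.
#' @param per_surname Share one draw per distinct surname (off by
#'   default: assignment is per post).
#' @return List with `tweets` (input plus `race` column) and `summary`
#'   (list: `n_total`, `n_matched`, `matched_fraction`, `counts` per
#'   label; unknowns are reported separately, never diluting the
#'   per-race counts).
#' @export
annotate_corpus <- function(tweets, table, seed = NULL, per_surname = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  nm <- normalize_surname(tweets$surname)
  row <- match(nm, table$surname)
  row[!nzchar(nm)] <- NA
  u <- runif(nrow(tweets))
  if (per_surname) {
    first <- match(nm, nm)  # index of first appearance
    u <- u[first]
  }
  race <- rep(RACE_UNKNOWN, nrow(tweets))
  hit <- which(!is.na(row))
  if (length(hit)) {
    p <- as.matrix(table[row[hit], RACE_LEVELS]) / 100
    cum <- p
    for (j in 2:ncol(cum)) cum[, j] <- cum[, j - 1L] + cum[, j]
    idx <- 1L + rowSums(u[hit] > cum)
    race[hit] <- RACE_LEVELS[pmin(idx, length(RACE_LEVELS))]
  }
  tweets$race <- race
  counts <- base::table(factor(race[race != RACE_UNKNOWN],
                               levels = RACE_LEVELS))
  list(
    tweets = tweets,
    summary = list(
      n_total = nrow(tweets),
      n_matched = length(hit),
      n_unknown = nrow(tweets) - length(hit),
      matched_fraction = if (nrow(tweets)) length(hit) / nrow(tweets) else 0,
      counts = as.list(setNames(as.integer(counts), names(counts)))
    )
  )
}
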