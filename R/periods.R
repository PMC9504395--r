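# Partition of the study window into four analysis sub-periods at the
# vaccine milestone dates, and five-number summaries for boxplot-style
# reporting.

#' Default sub-period boundary dates
#'
#' The three vaccine milestones that split the study window into four
#' regimes: the first efficacy-endpoint announcement (2020-11-09), the
#' first administered dose (2020-12-14), and the 100-million-doses mark
#' (2021-03-12).
#'
#' @return `Date` vector of length 3.
#' @export
default_period_boundaries <- function() {
  as.Date(c("2020-11-09", "2020-12-14", "2021-03-12"))
}

#' Map dates to study sub-periods
#'
#' Period 1 is before the first boundary, periods 2 and 3 between
#' consecutive boundaries, period 4 from the last boundary on. A boundary
#' date belongs to the later period: the event day starts the new regime.
#'
#' @param dates `Date` vector.
#' @param boundaries Ordered `Date` vector of length 3 (default
#'   [default_period_boundaries()]).
#' @param start,end Optional study window; dates outside it raise an error
#'   naming the offending date.
#' @return Integer vector of period labels 1-4.
#' @export
partition_periods <- function(dates, boundaries = default_period_boundaries(),
                              start = NULL, end = NULL) {
  dates <- as.Date(dates)
  boundaries <- as.Date(boundaries)
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("period boundaries must be strictly increasing", call. = FALSE)
  }
  if (!is.null(start) || !is.null(end)) {
    out_of_window <- (!is.null(start) & dates < as.Date(start)) |
      (!is.null(end) & dates > as.Date(end))
    if (any(out_of_window)) {
      stop("date outside the study window: ",
           format(dates[which(out_of_window)[1L]]), call. = FALSE)
    }
  }
  1L + findInterval(dates, boundaries)
}

#' Five-number summary of score values
#'
#' Minimum, first quartile, median, third quartile and maximum, with
#' quartiles from linear interpolation of order statistics
#' (`stats::quantile` type 7 by default; the type is switchable).
#'
#' @param values Numeric vector, length >= 1.
#' @param stratum,period Labels copied into the output row.
#' @param type Quantile algorithm type passed to [stats::quantile()].
#' @return One-row data frame `stratum`, `period`, `min`, `q1`, `median`,
#'   `q3`, `max`, `n`.
#' @export
quartile_summary <- function(values, stratum = NA_character_,
                             period = NA_integer_, type = 7) {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values)) {
    stop("quartile summary needs at least one non-missing value",
         call. = FALSE)
  }
  q <- quantile(values, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = type)
  data.frame(
    stratum = stratum, period = period,
    min = q[1L], q1 = q[2L], median = q[3L], q3 = q[4L], max = q[5L],
    n = length(values), stringsAsFactors = FALSE
  )
}

#' Per-period five-number summaries of a score table
#'
#' Splits a scored table by stratum and sub-period and summarises one
#' value column per cell.
#'
#' @param scores Data frame with `date`, `stratum` and the value column.
#' @param value_col Name of the column to summarise (e.g. `"pes"` or
#'   `"pss"`).
#' @param boundaries Period boundaries, see [partition_periods()].
#' @param date_col Name of the date column (`"date"` or `"week_start"`).
#' @param type Quantile type.
#' @return Data frame of one row per (stratum, period) present.
#' @export
period_quartiles <- function(scores, value_col,
                             boundaries = default_period_boundaries(),
                             date_col = "date", type = 7) {
  period <- partition_periods(scores[[date_col]], boundaries)
  cells <- split(seq_len(nrow(scores)),
                 list(stratum = scores$stratum, period = period),
                 drop = TRUE)
  rows <- lapply(cells, function(idx) {
    quartile_summary(scores[[value_col]][idx],
                     stratum = scores$stratum[idx[1L]],
                     period = period[idx[1L]], type = type)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$stratum, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}
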