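# Reading and writing the tabular formats the pipeline touches: tweet
# corpora (JSONL or CSV), population tables, census-style surname race
# distribution tables, daily value series, and score tables.

TWEET_COLUMNS <- c("message_id", "tweet_date", "tweet_text", "state",
                   "surname", "polarity")

empty_tweets <- function() {
  data.frame(
    message_id = character(0), tweet_date = as.Date(character(0)),
    tweet_text = character(0), state = character(0),
    surname = character(0), polarity = character(0),
    stringsAsFactors = FALSE
  )
}

#' Read a tweet corpus
#'
#' Reads one record per post from a JSONL file (one JSON object per line)
#' or a CSV file with a header. Mandatory fields are `message_id`,
#' `tweet_date` (ISO-8601 day) and `tweet_text`; `state`, `surname` and
#' `polarity` are optional per record and stored as `NA` when absent.
#' Malformed records (unparseable JSON, invalid dates, duplicated ids,
#' missing mandatory fields) are skipped, never silently: they are collected
#' with their line numbers in the `parse_errors` attribute and the identity
#' `rows in = rows parsed + rows reported` always holds.
#'
#' @param path Path to the corpus file.
#' @param format `"jsonl"`, `"csv"`, or `"auto"` (by file extension;
#'   `.jsonl`/`.ndjson`/`.json` are JSONL, everything else CSV).
#' @return A data frame with columns `message_id`, `tweet_date` (`Date`),
#'   `tweet_text`, `state`, `surname`, `polarity`, carrying attributes
#'   `parse_errors` (data frame `line`, `message`) and `n_skipped`.
#' @seealso [parse_errors()]
#' @export
read_tweets <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("jsonl", "ndjson", "json")) "jsonl" else "csv"
  }
  if (format == "jsonl") read_tweets_jsonl(path) else read_tweets_csv(path)
}

#' Parse errors collected while reading a corpus
#'
#' @param tweets A data frame returned by [read_tweets()].
#' @return Data frame with columns `line` and `message`, one row per
#'   skipped record.
#' @export
parse_errors <- function(tweets) {
  err <- attr(tweets, "parse_errors")
  if (is.null(err)) {
    err <- data.frame(line = integer(0), message = character(0))
  }
  err
}

finish_tweets <- function(df, errors, n_in) {
  # common validation once fields are in a raw character data frame with a
  # `line` column; returns the finished corpus with error bookkeeping
  add_err <- function(line, message) {
    errors[[length(errors) + 1L]] <<- data.frame(
      line = line, message = message, stringsAsFactors = FALSE)
  }
  if (nrow(df)) {
    d <- parse_iso_date(df$tweet_date)
    bad_date <- is.na(d)
    for (i in which(bad_date)) {
      add_err(df$line[i], paste0("invalid tweet_date '", df$tweet_date[i], "'"))
    }
    bad_id <- !bad_date & (is.na(df$message_id) | !nzchar(df$message_id))
    for (i in which(bad_id)) add_err(df$line[i], "empty message_id")
    keep <- !bad_date & !bad_id
    dup <- keep & duplicated(ifelse(keep, df$message_id, NA))
    for (i in which(dup)) {
      add_err(df$line[i], paste0("duplicate message_id '", df$message_id[i], "'"))
    }
    keep <- keep & !dup
    df <- df[keep, , drop = FALSE]
    d <- d[keep]
  } else {
    d <- as.Date(character(0))
  }
  out <- data.frame(
    message_id = as.character(df$message_id),
    tweet_date = d,
    tweet_text = as.character(df$tweet_text),
    state = as.character(df$state),
    surname = as.character(df$surname),
    polarity = as.character(df$polarity),
    stringsAsFactors = FALSE
  )
  # blank optional fields count as absent
  for (col in c("state", "surname", "polarity")) {
    out[[col]][!is.na(out[[col]]) & !nzchar(trimws(out[[col]]))] <- NA_character_
  }
  err <- if (length(errors)) do.call(rbind, errors) else
    data.frame(line = integer(0), message = character(0))
  err <- err[order(err$line), , drop = FALSE]
  rownames(err) <- NULL
  rownames(out) <- NULL
  stopifnot(n_in == nrow(out) + nrow(err))
  structure(out, parse_errors = err, n_skipped = nrow(err))
}

read_tweets_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines_keep <- nzchar(trimws(lines))
  idx <- which(lines_keep)
  errors <- list()
  recs <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    obj <- tryCatch(
      jsonlite::fromJSON(lines[idx[k]], simplifyVector = TRUE),
      error = function(e) e
    )
    if (inherits(obj, "error")) {
      errors[[length(errors) + 1L]] <- data.frame(
        line = idx[k], message = "malformed JSON", stringsAsFactors = FALSE)
      next
    }
    if (!all(c("message_id", "tweet_date", "tweet_text") %in% names(obj))) {
      errors[[length(errors) + 1L]] <- data.frame(
        line = idx[k], message = "missing mandatory field",
        stringsAsFactors = FALSE)
      next
    }
    get1 <- function(f) {
      v <- obj[[f]]
      if (is.null(v) || !length(v)) NA_character_ else as.character(v[[1]])
    }
    recs[[k]] <- data.frame(
      line = idx[k],
      message_id = get1("message_id"), tweet_date = get1("tweet_date"),
      tweet_text = get1("tweet_text"), state = get1("state"),
      surname = get1("surname"), polarity = get1("polarity"),
      stringsAsFactors = FALSE
    )
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  df <- if (length(recs)) do.call(rbind, recs) else
    cbind(line = integer(0), empty_tweets())
  finish_tweets(df, errors, sum(lines_keep))
}

read_tweets_csv <- function(path) {
  raw <- read.csv(path, colClasses = "character", stringsAsFactors = FALSE,
                  check.names = TRUE, na.strings = character(0))
  missing_cols <- setdiff(c("message_id", "tweet_date", "tweet_text"), names(raw))
  if (length(missing_cols)) {
    stop("corpus CSV lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(TWEET_COLUMNS, names(raw))) {
    raw[[col]] <- rep(NA_character_, nrow(raw))
  }
  raw$line <- seq_len(nrow(raw)) + 1L  # header is line 1
  finish_tweets(raw[, c("line", TWEET_COLUMNS)], list(), nrow(raw))
}

#' Write a tweet corpus as JSONL
#'
#' One JSON object per line; `NA` optional fields are omitted from the
#' object. Round-trips through [read_tweets()].
#'
#' @param tweets Tweet data frame (columns as in [read_tweets()]).
#' @param path Output path.
#' @export
write_tweets_jsonl <- function(tweets, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  df <- tweets[, intersect(TWEET_COLUMNS, names(tweets)), drop = FALSE]
  df$tweet_date <- format(df$tweet_date, "%Y-%m-%d")
  jsonlite::stream_out(df, con, na = "null", auto_unbox = TRUE,
                       verbose = FALSE)
  invisible(path)
}

#' Read a population table
#'
#' @param path CSV with columns `region,population`. Regions may be state
#'   codes, race labels, or `nation`.
#' @return Named numeric vector of populations.
#' @export
read_population_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("region", "population") %in% names(df))) {
    stop("population table needs columns region,population", call. = FALSE)
  }
  pop <- as.numeric(df$population)
  if (anyNA(pop) || any(pop <= 0)) {
    stop("populations must be positive numbers", call. = FALSE)
  }
  if (anyDuplicated(df$region)) {
    stop("duplicate region codes in population table: ",
         paste(unique(df$region[duplicated(df$region)]), collapse = ", "),
         call. = FALSE)
  }
  setNames(pop, df$region)
}

#' Read a census-style surname race distribution table
#'
#' Expects a CSV in the layout of the census last-name release: a name
#' column followed by percentage columns for the six race groups (White,
#' Black, Asian/Pacific Islander, American Indian/Alaska Native, two or
#' more races, Hispanic). Surnames are uppercased and diacritic-stripped;
#' rows whose six percentages do not sum to 100 within ±0.5 (e.g. rows with
#' suppressed small cells) are rejected with a warning; accepted rows are
#' rescaled so the six fields sum to exactly 100. When a surname appears
#' more than once the last row wins (with a warning).
#'
#' @param path CSV path with columns
#'   `name,white,black,api,aian,two_prace,hispanic`.
#' @param tolerance Maximum absolute deviation of a raw row sum from 100
#'   before the row is rejected.
#' @return Data frame with column `surname` plus the six percentage
#'   columns, each row summing to exactly 100.
#' @export
read_surname_table <- function(path, tolerance = 0.5) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", RACE_LEVELS)
  if (!all(need %in% names(df))) {
    stop("surname table needs columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  surname <- normalize_surname(df$name)
  pct <- as.matrix(df[, RACE_LEVELS])
  storage.mode(pct) <- "double"
  pct[is.na(pct)] <- 0
  if (any(pct < 0) || any(pct > 100)) {
    stop("surname table percentages must lie in [0, 100]", call. = FALSE)
  }
  sums <- rowSums(pct)
  bad <- abs(sums - 100) > tolerance
  if (any(bad)) {
    warning("rejected ", sum(bad), " surname row(s) with percentage sum ",
            "off 100 by more than ", tolerance, ": ",
            paste(surname[bad], collapse = ", "), call. = FALSE)
    surname <- surname[!bad]
    pct <- pct[!bad, , drop = FALSE]
    sums <- sums[!bad]
  }
  if (anyDuplicated(surname)) {
    dup <- unique(surname[duplicated(surname)])
    warning("duplicate surname(s), last row wins: ",
            paste(dup, collapse = ", "), call. = FALSE)
    keep <- !duplicated(surname, fromLast = TRUE)
    surname <- surname[keep]
    pct <- pct[keep, , drop = FALSE]
    sums <- sums[keep]
  }
  pct <- pct * (100 / sums)
  out <- data.frame(surname = surname, pct, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a daily value series
#'
#' @param path CSV with columns `date,value` (ISO dates, values >= 0).
#' @return Data frame `date` (`Date`, strictly increasing), `value`.
#' @export
read_daily_series <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "value") %in% names(df))) {
    stop("daily series needs columns date,value", call. = FALSE)
  }
  d <- parse_iso_date(df$date)
  if (anyNA(d)) {
    stop("unparseable date(s) in daily series: ",
         paste(head(df$date[is.na(d)], 3), collapse = ", "), call. = FALSE)
  }
  v <- as.numeric(df$value)
  if (anyNA(v) || any(v < 0)) {
    stop("daily series values must be non-negative", call. = FALSE)
  }
  if (is.unsorted(d, strictly = TRUE)) {
    stop("daily series dates must be strictly increasing", call. = FALSE)
  }
  data.frame(date = d, value = v, stringsAsFactors = FALSE)
}

#' Write a score table with a stable text representation
#'
#' Fixed column order (as given), reals printed with 12 significant
#' digits, dates in ISO form. Reading the file back with
#' [read_daily_scores()] reproduces strings, integers and dates exactly and
#' reals to 12 significant digits; two writes of the same table are
#' byte-identical.
#'
#' @param scores Data frame of scored rows.
#' @param path Output CSV path.
#' @export
write_daily_scores <- function(scores, path) {
  out <- scores
  for (col in names(out)) {
    v <- out[[col]]
    if (inherits(v, "Date")) {
      out[[col]] <- format(v, "%Y-%m-%d")
    } else if (is.double(v)) {
      s <- sprintf("%.12g", v)
      s[is.na(v)] <- NA_character_
      out[[col]] <- s
    }
  }
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write scores to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read back a score table written by [write_daily_scores()]
#'
#' @param path CSV path.
#' @return Data frame; a column named `date` or `week_start` is converted
#'   back to `Date`, numeric-looking columns to numeric.
#' @export
read_daily_scores <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in intersect(c("date", "week_start"), names(df))) {
    df[[col]] <- as.Date(df[[col]])
  }
  df
}
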