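# Keyword-lexicon tagging of the three vaccine discussion aspects, plus
# bigram/trigram frequency diagnostics used to validate a lexicon against
# a corpus.

TOPIC_NAMES <- c("vaccine_type", "phased_vaccination", "health_concern")

#' Default vaccine-aspect lexicon
#'
#' Keyword phrases for the three aspects of the vaccine discussion:
#' `vaccine_type` (vaccine brands), `phased_vaccination` (rollout and
#' administration), `health_concern` (side effects and health worries).
#' Matching is on whole tokens after [tokenize()], so the
#' "johnson &amp; johnson" brand is stored both in its escaped form and as
#' the two-token phrase the tokenizer produces.
#'
#' @return Named list of lowercase phrase vectors, one per topic.
#' @export
default_lexicon <- function() {
  list(
    vaccine_type = c("pfizer", "moderna", "johnson amp johnson",
                     "johnson johnson", "janssen", "biotech"),
    phased_vaccination = c("frontline", "phased", "first dose", "healthcare",
                           "old", "second dose", "operation", "registration",
                           "cvs", "pharmacy", "administration", "essential",
                           "medical condition", "front line", "health care"),
    health_concern = c("side effect", "mask", "die", "warp speed", "warp",
                       "fever", "tiredness", "headache", "muscle pain",
                       "chills")
  )
}

#' Read a topic lexicon from CSV
#'
#' @param path CSV with columns `topic,phrase`.
#' @return Named list of lowercase phrase vectors.
#' @export
read_lexicon <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("topic", "phrase") %in% names(df))) {
    stop("lexicon needs columns topic,phrase", call. = FALSE)
  }
  lex <- split(tolower(trimws(df$phrase)), df$topic)
  lex[order(match(names(lex), TOPIC_NAMES))]
}

# normalise a phrase or text to its token string, padded with sentinels so
# fixed-string search respects token boundaries
token_string <- function(texts) {
  toks <- tokenize_all(texts)
  vapply(toks, function(t) paste0(" ", paste(t, collapse = " "), " "),
         character(1))
}

#' Tag a text with discussion topics
#'
#' A topic is assigned iff any of its lexicon phrases occurs in the text as
#' a whole-token phrase (multi-word phrases must match consecutive tokens);
#' a text can receive zero to all topics. Matching is case-insensitive via
#' [tokenize()], so `"old"` never matches inside `"golden"`.
#'
#' @param text A single character string.
#' @param lexicon Named list of phrase vectors; default [default_lexicon()].
#' @return Character vector of matched topic names (possibly empty), in
#'   lexicon order.
#' @export
#' @examples
#' tag_topics("Got my first dose of Pfizer today")
tag_topics <- function(text, lexicon = default_lexicon()) {
  stopifnot(length(text) == 1L)
  m <- topic_matches(text, lexicon)
  names(lexicon)[m[1L, ]]
}

# logical matrix texts x topics
topic_matches <- function(texts, lexicon) {
  padded <- token_string(texts)
  m <- matrix(FALSE, nrow = length(texts), ncol = length(lexicon),
              dimnames = list(NULL, names(lexicon)))
  for (k in seq_along(lexicon)) {
    needles <- unique(token_string(lexicon[[k]]))
    needles <- needles[needles != "  "]  # phrases that tokenize to nothing
    for (nd in needles) {
      m[, k] <- m[, k] | grepl(nd, padded, fixed = TRUE)
    }
  }
  m
}

#' Annotate a corpus with topic tags
#'
#' Adds a `topics` column (semicolon-joined topic names, `NA` when no
#' topic matches) to a tweet data frame.
#'
#' @param tweets Tweet data frame.
#' @param lexicon Named list of phrase vectors.
#' @return The input data frame with a `topics` column.
#' @export
annotate_topics <- function(tweets, lexicon = default_lexicon()) {
  m <- topic_matches(tweets$tweet_text, lexicon)
  tags <- apply(m, 1L, function(r) paste(colnames(m)[r], collapse = ";"))
  tweets$topics <- ifelse(nzchar(tags), tags, NA_character_)
  tweets
}

# small built-in stop-word list, applied to n-gram extraction only
NGRAM_STOPWORDS <- c(
  "the", "a", "an", "and", "or", "of", "to", "in", "on", "for", "is",
  "are", "was", "were", "be", "been", "am", "i", "my", "me", "we", "our",
  "you", "your", "it", "its", "this", "that", "with", "at", "by", "from",
  "as", "but", "not", "so", "if", "they", "their", "he", "she", "his",
  "her", "have", "has", "had", "do", "does", "did", "will", "would",
  "can", "could", "about", "just"
)

#' Most frequent word n-grams in a corpus
#'
#' Computes bigrams or trigrams over the tokenized text of each post
#' (never across posts), after dropping a small built-in stop-word list,
#' and returns the `top_k` most frequent. Ties are broken
#' lexicographically, so the ranking is deterministic.
#'
#' @param tweets Tweet data frame, or a character vector of texts.
#' @param n N-gram order, 2 or 3.
#' @param top_k Number of top phrases to return.
#' @return Data frame `phrase`, `count`, ranked by descending count.
#' @export
extract_ngrams <- function(tweets, n = 2, top_k = 50) {
  stopifnot(n %in% c(2, 3), top_k >= 1)
  texts <- if (is.data.frame(tweets)) tweets$tweet_text else tweets
  toks <- tokenize_all(texts)
  toks <- lapply(toks, function(t) t[!t %in% NGRAM_STOPWORDS])
  grams <- unlist(lapply(toks, function(t) {
    if (length(t) < n) return(character(0))
    starts <- seq_len(length(t) - n + 1L)
    vapply(starts, function(s) paste(t[s:(s + n - 1L)], collapse = " "),
           character(1))
  }))
  if (!length(grams)) {
    return(data.frame(phrase = character(0), count = integer(0)))
  }
  tab <- table(grams)
  out <- data.frame(phrase = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$phrase), , drop = FALSE]
  out <- head(out, top_k)
  rownames(out) <- NULL
  out
}
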