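# Multinomial Naive Bayes polarity classifier. The pipeline's recommended
# mode is to accept precomputed polarity labels on input; the classifier
# makes the pipeline self-contained when no labels are supplied.

#' Tokenize text
#'
#' Lowercases, splits on runs of non-alphanumeric characters, keeps tokens
#' of length >= 2. Deterministic; `"COVID-19 vaccine"` becomes
#' `c("covid", "19", "vaccine")`.
#'
#' @param text A single character string.
#' @return Character vector of tokens (empty for empty text).
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  tokenize_all(text)[[1L]]
}

#' Tokenize a vector of texts
#'
#' Vectorised form of [tokenize()].
#'
#' @param texts Character vector.
#' @return List of token character vectors, one per input text.
#' @export
tokenize_all <- function(texts) {
  texts[is.na(texts)] <- ""
  parts <- strsplit(tolower(texts), "[^a-z0-9]+")
  lapply(parts, function(t) t[nchar(t) >= 2L])
}

# floor for per-token log-likelihoods so classification stays total when
# smoothing = 0 leaves zero-probability tokens (log(5e-324) ~ -744.4)
LOGLIK_FLOOR <- -745

#' Train a multinomial Naive Bayes polarity model
#'
#' Class priors are label relative frequencies; token likelihoods use
#' additive (Laplace) smoothing:
#' `P(token | class) = (count + s) / (class total + s * |V|)` over the
#' training vocabulary V.
#'
#' @param texts Character vector of training documents.
#' @param labels Polarity labels, one of `positive`, `neutral`, `negative`;
#'   every class must be represented.
#' @param smoothing Additive smoothing pseudo-count `s` (default 1;
#'   `s = 0` is accepted, unseen-token log-likelihoods are floored).
#' @return An object of class `nb_model`: list with `classes`, `prior`,
#'   `loglik` (|V| x 3 matrix), `vocab`, `smoothing`.
#' @export
train_nb <- function(texts, labels, smoothing = 1) {
  stopifnot(length(texts) == length(labels), smoothing >= 0)
  labels <- as.character(labels)
  if (!all(labels %in% POLARITY_LEVELS)) {
    stop("labels must be one of: ", paste(POLARITY_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  n_class <- table(factor(labels, levels = POLARITY_LEVELS))
  if (any(n_class == 0)) {
    stop("no training documents for class: ",
         paste(names(n_class)[n_class == 0], collapse = ", "), call. = FALSE)
  }
  toks <- tokenize_all(texts)
  vocab <- sort(unique(unlist(toks)))
  counts <- matrix(0, nrow = length(vocab), ncol = length(POLARITY_LEVELS),
                   dimnames = list(vocab, POLARITY_LEVELS))
  for (cl in POLARITY_LEVELS) {
    tt <- unlist(toks[labels == cl])
    if (length(tt)) {
      tab <- table(factor(tt, levels = vocab))
      counts[, cl] <- as.numeric(tab)
    }
  }
  denom <- colSums(counts) + smoothing * length(vocab)
  lik <- sweep(counts + smoothing, 2, denom, "/")
  loglik <- suppressWarnings(log(lik))
  loglik[loglik < LOGLIK_FLOOR | !is.finite(loglik)] <- LOGLIK_FLOOR
  structure(
    list(
      classes = POLARITY_LEVELS,
      prior = as.numeric(n_class) / length(labels),
      loglik = loglik,
      vocab = vocab,
      smoothing = smoothing
    ),
    class = "nb_model"
  )
}

#' Classify text polarity
#'
#' Posterior proportional to `P(class) * prod P(token | class)` over
#' in-vocabulary tokens, renormalised; out-of-vocabulary tokens are
#' skipped (training smoothing already reserved their mass). Text with no
#' in-vocabulary tokens gets the class priors as posterior. Ties are broken
#' in the fixed order positive > neutral > negative.
#'
#' @param model An `nb_model` from [train_nb()].
#' @param text A single character string.
#' @return List with `polarity` and `posterior` (named 3-vector summing
#'   to 1).
#' @export
classify <- function(model, text) {
  stopifnot(inherits(model, "nb_model"), length(text) == 1L)
  post <- classify_all(model, text)
  list(
    polarity = post$polarity[1L],
    posterior = setNames(
      as.numeric(post[1L, paste0("p_", model$classes)]), model$classes)
  )
}

#' Classify a vector of texts
#'
#' @param model An `nb_model`.
#' @param texts Character vector.
#' @return Data frame with columns `polarity`, `p_positive`, `p_neutral`,
#'   `p_negative`.
#' @export
classify_all <- function(model, texts) {
  stopifnot(inherits(model, "nb_model"))
  toks <- tokenize_all(texts)
  log_prior <- log(model$prior)
  scores <- t(vapply(toks, function(t) {
    idx <- match(t, model$vocab)
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      log_prior + colSums(model$loglik[idx, , drop = FALSE])
    } else {
      log_prior
    }
  }, numeric(length(model$classes))))
  scores <- scores - apply(scores, 1L, max)
  post <- exp(scores)
  post <- post / rowSums(post)
  pick <- apply(post, 1L, which.max)  # first max wins: positive > neutral > negative
  out <- data.frame(polarity = model$classes[pick], stringsAsFactors = FALSE)
  for (k in seq_along(model$classes)) {
    out[[paste0("p_", model$classes[k])]] <- post[, k]
  }
  out
}

#' Serialise a Naive Bayes model to JSON
#'
#' @param model An `nb_model`.
#' @param path Output path.
#' @export
write_nb_model <- function(model, path) {
  stopifnot(inherits(model, "nb_model"))
  obj <- list(
    classes = model$classes,
    prior = model$prior,
    vocab = model$vocab,
    loglik = unname(model$loglik),
    smoothing = model$smoothing
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a Naive Bayes model from JSON
#'
#' @param path Path written by [write_nb_model()].
#' @return An `nb_model`.
#' @export
read_nb_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  loglik <- obj$loglik
  if (is.null(dim(loglik))) {  # single-token vocabulary simplifies to a vector
    loglik <- matrix(loglik, ncol = length(obj$classes))
  }
  dimnames(loglik) <- list(obj$vocab, obj$classes)
  structure(
    list(classes = obj$classes, prior = obj$prior, loglik = loglik,
         vocab = obj$vocab, smoothing = obj$smoothing),
    class = "nb_model"
  )
}
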