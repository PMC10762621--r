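char_ngrams <- function(norm, n = 3L) {
  # overlapping character n-grams; short strings fall back to the whole string
  out <- lapply(norm, function(x) {
    L <- nchar(x)
    if (L < n) return(if (nzchar(x)) x else character(0))
    substring(x, seq_len(L - n + 1L), seq.int(n, L))
  })
  out
}

#' Train the stand-in text classifier
#'
#' A deterministic multinomial naive Bayes over bag-of-character-trigrams
#' with additive (Laplace) smoothing. It stands in for the original
#' transformer-based cleaning models in a desk-verifiable form and is used
#' only for reported comparison against the rule verdicts -- it never
#' overrides them.
#'
#' @param texts character vector of training documents.
#' @param labels character vector of class labels (at least two distinct).
#' @param n n-gram size (default 3).
#' @param alpha additive smoothing constant.
#' @return object of class `tg_classifier`.
#' @export
train_stand_in_classifier <- function(texts, labels, n = 3L, alpha = 1) {
  stopifnot(length(texts) == length(labels), length(texts) > 0L)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("training data must contain at least two labels", call. = FALSE)
  }
  grams <- char_ngrams(normalize_text(texts), n)
  vocab <- sort(unique(unlist(grams)))
  counts <- matrix(0, nrow = length(classes), ncol = length(vocab),
                   dimnames = list(classes, vocab))
  for (i in seq_along(grams)) {
    if (!length(grams[[i]])) next
    tab <- table(grams[[i]])
    counts[labels[i], names(tab)] <- counts[labels[i], names(tab)] +
      as.numeric(tab)
  }
  log_lik <- log(counts + alpha) -
    log(rowSums(counts) + alpha * length(vocab))
  log_prior <- log(as.numeric(table(factor(labels, classes))) /
                     length(labels))
  structure(list(classes = classes, vocab = vocab, log_lik = log_lik,
                 log_prior = log_prior, n = n, alpha = alpha,
                 # unseen-gram likelihood per class
                 log_unseen = log(alpha) -
                   log(rowSums(counts) + alpha * length(vocab))),
            class = "tg_classifier")
}

#' Classify text with the stand-in classifier
#'
#' @param classifier a `tg_classifier` from [train_stand_in_classifier()].
#' @param texts character vector.
#' @return character vector of predicted labels (ties broken by label order,
#'   deterministically).
#' @export
classify_text <- function(classifier, texts) {
  stopifnot(inherits(classifier, "tg_classifier"))
  grams <- char_ngrams(normalize_text(texts), classifier$n)
  vapply(grams, function(g) {
    scores <- classifier$log_prior
    if (length(g)) {
      known <- g %in% classifier$vocab
      if (any(known)) {
        tab <- table(g[known])
        scores <- scores +
          as.numeric(classifier$log_lik[, names(tab), drop = FALSE] %*%
                       as.numeric(tab))
      }
      scores <- scores + sum(!known) * classifier$log_unseen
    }
    classifier$classes[which.max(scores)]
  }, character(1))
}
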