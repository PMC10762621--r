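#' Build a search clause
#'
#' A clause is either a single keyword category (kept if any term of that
#' category occurs in the text) or a pair of categories combined with AND
#' (each side is an OR over its terms).
#'
#' @param categories one or two lexicon category codes.
#' @return list of class `tg_clause` with `kind`, `categories` and a display
#'   `label` such as `"II-a"` or `"I-a+II-b"`.
#' @export
search_clause <- function(categories) {
  categories <- as.character(categories)
  if (!length(categories) %in% 1:2 ||
      !all(categories %in% LEXICON_CATEGORIES) ||
      anyDuplicated(categories)) {
    stop("a clause needs one or two distinct lexicon categories",
         call. = FALSE)
  }
  structure(list(kind = if (length(categories) == 1L) "single" else "pair",
                 categories = categories,
                 label = paste(categories, collapse = "+")),
            class = "tg_clause")
}

#' The default search strategy
#'
#' Three single-category clauses (I-a, II-a, IV-a) and eleven pairwise AND
#' combinations -- the canonical keyword strategy for hypertriglyceridemia
#' consultation retrieval.
#'
#' @return list of class `tg_strategy` (an ordered list of [search_clause()]s).
#' @export
default_strategy <- function() {
  specs <- list(
    "I-a", "II-a", "IV-a",
    c("I-a", "II-a"), c("I-a", "II-b"), c("I-a", "III"),
    c("I-a", "IV-a"), c("I-a", "IV-b"),
    c("II-a", "I-b"), c("II-a", "III"), c("II-a", "IV-a"), c("II-a", "IV-b"),
    c("IV-a", "I-b"), c("IV-a", "II-b")
  )
  structure(lapply(specs, search_clause), class = "tg_strategy")
}

#' Read a search strategy from a config file
#'
#' @param path JSON file: an array of arrays of category codes, e.g.
#'   `[["II-a"], ["I-a","II-b"]]`.
#' @return a `tg_strategy`.
#' @export
load_strategy <- function(path) {
  specs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!length(specs)) stop("strategy must be nonempty", call. = FALSE)
  structure(lapply(specs, function(s) search_clause(unlist(s))),
            class = "tg_strategy")
}

#' Match one lexicon category against text
#'
#' @param text character vector of *normalized* text (see [normalize_text()]).
#' @param lexicon a `tg_lexicon`.
#' @param category a category code present in the lexicon.
#' @return logical vector: `TRUE` where any term of the category occurs as a
#'   substring.
#' @export
match_category <- function(text, lexicon, category) {
  terms <- lexicon_terms(lexicon, category)
  hit <- logical(length(text))
  for (term in terms) {
    if (all(hit)) break
    hit <- hit | grepl(term, text, fixed = TRUE)
  }
  hit
}

#' Match one search clause against text
#'
#' Single clauses reduce to [match_category()]; pair clauses are the logical
#' AND of their two category matches.
#'
#' @inheritParams match_category
#' @param clause a [search_clause()].
#' @return logical vector.
#' @export
match_clause <- function(text, lexicon, clause) {
  stopifnot(inherits(clause, "tg_clause"))
  hit <- match_category(text, lexicon, clause$categories[1])
  if (clause$kind == "pair") {
    hit <- hit & match_category(text, lexicon, clause$categories[2])
  }
  hit
}

#' Retrieve posts by keyword strategy
#'
#' A post is kept iff at least one clause of the strategy matches its
#' (normalized) query text. Responses are not searched: the strategy targets
#' consultations; responses enter the pipeline at later stages.
#'
#' @param posts list of `tg_post` objects.
#' @param strategy a `tg_strategy`; default [default_strategy()].
#' @param lexicon a `tg_lexicon`; default bundled English lexicon.
#' @return list with `kept` (posts, input order preserved) and `matches`
#'   (named list keyed by post_id: character vector of the labels of every
#'   matching clause -- empty for dropped posts).
#' @export
retrieve <- function(posts, strategy = default_strategy(),
                     lexicon = default_lexicon()) {
  stopifnot(inherits(strategy, "tg_strategy"))
  text <- normalize_text(vapply(posts, function(p) p$query_text, character(1)))
  labels <- vapply(strategy, function(cl) cl$label, character(1))
  hits <- matrix(FALSE, nrow = length(posts), ncol = length(strategy))
  for (j in seq_along(strategy)) {
    hits[, j] <- match_clause(text, lexicon, strategy[[j]])
  }
  any_hit <- if (length(posts)) rowSums(hits) > 0L else logical(0)
  matches <- lapply(seq_along(posts), function(i) labels[hits[i, ]])
  names(matches) <- vapply(posts, function(p) p$post_id, character(1))
  list(kept = posts[any_hit], matches = matches)
}
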