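LEXICON_CATEGORIES <- c("I-a", "I-b", "II-a", "II-b", "III", "IV-a", "IV-b")

#' Load a keyword lexicon
#'
#' The lexicon is the seven-category keyword system that powers retrieval,
#' inclusion rules and drug-class mapping:
#' \describe{
#'   \item{I-a / I-b}{disease terms (hypertriglyceridemia proper; broader
#'     hyperlipidemia terms)}
#'   \item{II-a / II-b}{diagnosis and treatment indicators (triglyceride
#'     terms; blood-lipid terms)}
#'   \item{III}{lifestyle intervention terms (diet, food)}
#'   \item{IV-a / IV-b}{therapeutic drugs (fibrates; non-fibrate
#'     lipid-lowering drugs)}
#' }
#' Terms are normalized via [normalize_text()] and de-duplicated within each
#' category. All seven categories must be present and nonempty.
#'
#' @param path JSON file mapping category code to an array of terms, plus an
#'   optional `"language"` key (`"en"` or `"zh"`).
#' @return object of class `tg_lexicon`: list with `language` and `terms`
#'   (named list of character vectors).
#' @seealso [default_lexicon()] for the two bundled lexicons.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("no such lexicon file: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  language <- raw$language %||% "en"
  missing <- setdiff(LEXICON_CATEGORIES, names(raw))
  if (length(missing)) {
    stop("lexicon is missing categor", if (length(missing) > 1) "ies " else "y ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  terms <- lapply(raw[LEXICON_CATEGORIES], function(x) {
    x <- unique(normalize_text(as.character(x)))
    x[nzchar(x)]
  })
  bad <- names(terms)[vapply(terms, length, integer(1)) == 0L]
  if (length(bad)) {
    stop("lexicon category has no usable terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(language = language, terms = terms), class = "tg_lexicon")
}

#' Bundled lexicons
#'
#' Two lexicons ship with the package: `"en"` (used throughout the tests for
#' readability) and `"zh"` (the Chinese keyword system the English one
#' mirrors).
#'
#' @param language `"en"` or `"zh"`.
#' @return a `tg_lexicon`.
#' @export
default_lexicon <- function(language = c("en", "zh")) {
  language <- match.arg(language)
  load_lexicon(system.file("extdata", paste0("lexicon_", language, ".json"),
                           package = "tglisten", mustWork = TRUE))
}

#' @export
print.tg_lexicon <- function(x, ...) {
  cat(sprintf("<tg_lexicon [%s]: %s terms in %d categories>\n", x$language,
              sum(vapply(x$terms, length, integer(1))), length(x$terms)))
  invisible(x)
}

lexicon_terms <- function(lexicon, category) {
  if (!category %in% names(lexicon$terms)) {
    stop("unknown lexicon category: ", category, call. = FALSE)
  }
  lexicon$terms[[category]]
}
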