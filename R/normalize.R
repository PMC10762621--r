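#' Normalize consultation text
#'
#' Canonical text form used by every matcher and extractor in the package:
#' case-folded, full-width (CJK compatibility) ASCII mapped to half-width,
#' runs of whitespace collapsed to single spaces, and leading/trailing
#' whitespace stripped. The function is idempotent and never increases the
#' character count of its input.
#'
#' Substring matching on this normalized form is the package's uniform
#' matching strategy: Chinese consultation text has no word boundaries, so
#' no tokenizer is assumed, and the same rule is applied to English text.
#'
#' @param text character vector. `NA` is passed through as `NA`.
#' @return character vector of the same length.
#' @examples
#' normalize_text("High  TG ")   # "high tg"
#' normalize_text("ＴＧ　2.5")  # full-width "TG 2.5" -> "tg 2.5"
#' @export
normalize_text <- function(text) {
  if (length(text) == 0L) return(character(0))
  stopifnot(is.character(text))
  out <- vapply(text, function(x) {
    if (is.na(x)) return(NA_character_)
    if (!nzchar(x)) return("")
    cp <- utf8ToInt(x)
    # full-width ASCII block U+FF01..U+FF5E -> U+0021..U+007E; ideographic space
    fw <- cp >= 0xFF01L & cp <= 0xFF5EL
    cp[fw] <- cp[fw] - 0xFEE0L
    cp[cp == 0x3000L] <- 0x20L
    intToUtf8(cp)
  }, character(1), USE.NAMES = FALSE)
  out <- tolower(out)
  out <- gsub("[[:space:]]+", " ", out)
  trimws(out)
}
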