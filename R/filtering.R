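FILTER_RULES <- c("duplicate", "advertisement", "popular_science",
                  "non_topic", "none")

has_condition_evidence <- function(norm, config) {
  # any extracted TG value, any symptom term, or a personal-illness pattern
  if (length(extract_tg_values_one(norm))) return(TRUE)
  if (length(match_vocab(norm, config$symptoms))) return(TRUE)
  any(vapply(config$illness_patterns,
             function(p) grepl(p, norm, perl = TRUE), logical(1)))
}

#' Drop duplicate post IDs
#'
#' First occurrence of each `post_id` is kept; later occurrences are dropped
#' with rule `duplicate`.
#'
#' @param posts list of `tg_post` objects (ordered stream).
#' @return list with `kept` (posts) and `decisions` (data.frame `post_id`,
#'   `verdict`, `rule_fired`).
#' @export
drop_duplicates <- function(posts) {
  ids <- vapply(posts, function(p) p$post_id, character(1))
  dup <- duplicated(ids)
  decisions <- data.frame(post_id = ids,
                          verdict = ifelse(dup, "drop", "keep"),
                          rule_fired = ifelse(dup, "duplicate", "none"),
                          stringsAsFactors = FALSE)
  list(kept = posts[!dup], decisions = decisions)
}

#' Advertisement rule
#'
#' A post is an advertisement iff a link token or promotion marker is
#' present AND there is no patient-condition evidence (no TG value, no
#' symptom term, no personal-illness phrasing).
#'
#' @param post a `tg_post`.
#' @param config a `tg_config` (marker lists are editable there).
#' @return logical.
#' @export
is_advertisement <- function(post, config = load_config()) {
  norm <- normalize_text(post$query_text)
  markers <- c(config$link_tokens, config$promo_markers)
  has_marker <- any(vapply(markers, function(t) grepl(t, norm, fixed = TRUE),
                           logical(1)))
  has_marker && !has_condition_evidence(norm, config)
}

#' Popular-science rule
#'
#' A post is popular science iff encyclopedic/definitional marker phrasing is
#' present AND there is no personal-condition evidence.
#'
#' @inheritParams is_advertisement
#' @return logical.
#' @export
is_popular_science <- function(post, config = load_config()) {
  norm <- normalize_text(post$query_text)
  has_marker <- any(vapply(config$science_markers,
                           function(t) grepl(t, norm, fixed = TRUE),
                           logical(1)))
  has_marker && !has_condition_evidence(norm, config)
}

#' Non-topic rule
#'
#' A post is non-topic iff at least one TG value was extracted AND every
#' extracted value is below the inclusion threshold (1.7 mmol/L). Posts with
#' no extractable TG value are not non-topic by this rule.
#'
#' @inheritParams is_advertisement
#' @param threshold inclusion threshold in mmol/L.
#' @return logical.
#' @export
is_non_topic <- function(post, config = load_config(), threshold = 1.7) {
  vals <- extract_tg_values_one(normalize_text(post$query_text))
  length(vals) > 0L && all(vals < threshold)
}

#' Apply all exclusion rules
#'
#' Fixed precedence: duplicate, then advertisement, then popular science,
#' then non-topic. The first rule that fires is recorded; a post is kept iff
#' no rule fires. Idempotent on its own kept output.
#'
#' @param posts list of `tg_post` objects.
#' @param config a `tg_config`.
#' @return list with `kept` (posts) and `decisions` (data.frame `post_id`,
#'   `verdict`, `rule_fired`; one row per input post, input order).
#' @export
apply_filters <- function(posts, config = load_config()) {
  ids <- vapply(posts, function(p) p$post_id, character(1))
  rule <- rep("none", length(posts))
  dup <- duplicated(ids)
  rule[dup] <- "duplicate"
  for (i in seq_along(posts)) {
    if (rule[i] != "none") next
    if (is_advertisement(posts[[i]], config)) {
      rule[i] <- "advertisement"
    } else if (is_popular_science(posts[[i]], config)) {
      rule[i] <- "popular_science"
    } else if (is_non_topic(posts[[i]], config)) {
      rule[i] <- "non_topic"
    }
  }
  decisions <- data.frame(post_id = ids,
                          verdict = ifelse(rule == "none", "keep", "drop"),
                          rule_fired = rule,
                          stringsAsFactors = FALSE)
  list(kept = posts[rule == "none"], decisions = decisions)
}

#' Write filter decisions as CSV
#'
#' @param decisions decisions data.frame from [apply_filters()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  utils::write.csv(decisions, path, row.names = FALSE)
  invisible(path)
}
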