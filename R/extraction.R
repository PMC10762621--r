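MG_DL_PER_MMOL_L <- 88.57  # standard triglyceride conversion factor

TG_TERM_PATTERN <- "(triglycerides|triglyceride|triacylglycerols|triacylglycerol|tg|甘油三酯|三酸甘油脂|甘油三脂)"
NUMBER_PATTERN <- "[0-9]+(\\.[0-9]+)?"

match_vocab <- function(norm_text, vocab) {
  # vocab: named list of character vectors -> labels whose any term occurs
  hit <- vapply(vocab, function(terms) {
    any(vapply(terms, function(t) grepl(t, norm_text, fixed = TRUE),
               logical(1)))
  }, logical(1))
  names(vocab)[hit]
}

#' Extract triglyceride lab values from text
#'
#' Captures numbers adjacent to (following) a triglyceride term, within the
#' same sentence and at most 60 characters away. Values with an explicit
#' `mmol/l` unit are kept as-is; `mg/dl` values are divided by 88.57;
#' unitless numbers are accepted as mmol/L only when in \[0.1, 100\].
#' Numbers denoting ages, gestation weeks or percentages are skipped.
#'
#' @param text character; raw or normalized (normalization is applied).
#' @return for a single string, a numeric vector of values in order of
#'   appearance (possibly empty); for a vector input, a list of such vectors.
#' @examples
#' extract_tg_values("triglyceride 2.4 mmol/L")      # 2.4
#' extract_tg_values("TG 150 mg/dL")                 # 1.6936...
#' extract_tg_values("TG was 1.5 then 2.4 mmol/L")   # c(1.5, 2.4)
#' @export
extract_tg_values <- function(text) {
  out <- lapply(normalize_text(text), extract_tg_values_one)
  if (length(text) == 1L) out[[1]] else out
}

extract_tg_values_one <- function(norm) {
  if (is.na(norm) || !nzchar(norm)) return(numeric(0))
  term_pat <- paste0("(^|[^a-z])", TG_TERM_PATTERN)
  m <- gregexpr(term_pat, norm, perl = TRUE)[[1]]
  if (m[1] == -1L) return(numeric(0))
  ends <- m + attr(m, "match.length") - 1L
  vals <- numeric(0)
  pos <- integer(0)
  for (e in ends) {
    window <- substr(norm, e + 1L, e + 60L)
    # stop at a sentence boundary (period/question/exclamation before a
    # space or end -- decimal points inside numbers do not qualify)
    stop_at <- regexpr("[.?!](\\s|$)", window, perl = TRUE)
    if (stop_at > 0L) window <- substr(window, 1L, stop_at - 1L)
    nm <- gregexpr(NUMBER_PATTERN, window, perl = TRUE)[[1]]
    if (nm[1] == -1L) next
    lens <- attr(nm, "match.length")
    for (k in seq_along(nm)) {
      after <- substr(window, nm[k] + lens[k], nm[k] + lens[k] + 12L)
      if (grepl("^\\s*(years?|year-old|weeks?|%)", after)) next
      num <- as.numeric(substr(window, nm[k], nm[k] + lens[k] - 1L))
      if (grepl("^\\s*mg/dl", after)) {
        val <- num / MG_DL_PER_MMOL_L
      } else if (grepl("^\\s*mmol/l", after)) {
        val <- num
      } else if (num >= 0.1 && num <= 100) {
        val <- num  # unitless but adjacent to a TG term: assume mmol/L
      } else {
        next
      }
      abs_pos <- e + nm[k]
      if (!abs_pos %in% pos) {
        vals <- c(vals, val)
        pos <- c(pos, abs_pos)
      }
    }
  }
  vals[order(pos)]
}

#' Extract patient gender and proxy status
#'
#' Relational cues (`"my father"`, `"my wife"`, ...) assign the *patient's*
#' gender via the bundled relation table and mark the consultation as a
#' proxy; direct self-descriptions (`"i am a woman"`, `"45 year old man"`)
#' assign gender with `is_proxy = FALSE`. Relational cues take precedence
#' (a proxy post describes the patient, not the poster). No cue gives
#' `("unknown", FALSE)`.
#'
#' @param text a single string.
#' @param config a `tg_config`.
#' @return list with `gender` (`"male"|"female"|"unknown"`), `is_proxy`,
#'   `relation` (`NA` unless proxy).
#' @export
extract_gender <- function(text, config = load_config()) {
  norm <- normalize_text(text)
  rels <- config$relations
  pats <- paste0("my ", names(rels))
  pos <- vapply(pats, function(p) {
    r <- regexpr(p, norm, fixed = TRUE)
    if (r < 0L) NA_integer_ else as.integer(r)
  }, integer(1))
  if (any(!is.na(pos))) {
    rel <- names(rels)[which.min(pos)]  # earliest cue wins
    return(list(gender = unname(unlist(rels[rel])), is_proxy = TRUE,
                relation = rel))
  }
  for (g in c("female", "male")) {  # "woman" contains "man": female first
    if (any(vapply(config$gender_direct[[g]],
                   function(p) grepl(p, norm, fixed = TRUE), logical(1)))) {
      return(list(gender = g, is_proxy = FALSE, relation = NA_character_))
    }
  }
  list(gender = "unknown", is_proxy = FALSE, relation = NA_character_)
}

#' Extract patient age in years
#'
#' Direct patterns (`"45 years old"`, `"45-year-old"`, `"age 45"`) give the
#' exact age; indirect band phrases (`"in my twenties"`) map to band
#' midpoints via the bundled table. With multiple direct matches the first is
#' used. Returns `NA` when no cue is present.
#'
#' @inheritParams extract_gender
#' @return numeric scalar or `NA`.
#' @export
extract_age <- function(text, config = load_config()) {
  norm <- normalize_text(text)
  m <- regexpr("([0-9]{1,3})[ -]years?([ -]old|[ -]of[ -]age)", norm,
               perl = TRUE)
  if (m > 0L) {
    return(as.numeric(sub("^([0-9]{1,3}).*", "\\1",
                          regmatches(norm, m))))
  }
  m <- regexpr("\\baged? ([0-9]{1,3})", norm, perl = TRUE)
  if (m > 0L) {
    return(as.numeric(gsub("[^0-9]", "", regmatches(norm, m))))
  }
  for (phrase in names(config$age_indirect)) {
    if (grepl(phrase, norm, fixed = TRUE)) {
      return(as.numeric(config$age_indirect[[phrase]]))
    }
  }
  NA_real_
}

#' Extract pregnancy status
#' @inheritParams extract_gender
#' @return logical.
#' @export
extract_pregnancy <- function(text, config = load_config()) {
  norm <- normalize_text(text)
  any(vapply(config$pregnancy_terms,
             function(t) grepl(t, norm, fixed = TRUE), logical(1)))
}

#' Extract symptom locations
#'
#' Head symptoms (dizziness, headache), chest symptoms (chest tightness,
#' chest pain, palpitation, shortness of breath) and an extensible `other`
#' list.
#'
#' @inheritParams extract_gender
#' @return character vector, subset of `c("head", "chest", "other")`.
#' @export
extract_symptoms <- function(text, config = load_config()) {
  match_vocab(normalize_text(text), config$symptoms)
}

#' Extract secondary conditions
#'
#' Coronary heart disease / myocardial infarction map to `ascvd_cardiac`;
#' cerebral infarction / stroke to `ascvd_cerebral`; pancreatitis to
#' `pancreatitis`.
#'
#' @inheritParams extract_gender
#' @return character vector, subset of
#'   `c("ascvd_cardiac", "ascvd_cerebral", "pancreatitis")`.
#' @export
extract_secondary <- function(text, config = load_config()) {
  match_vocab(normalize_text(text), config$secondary)
}

extract_chol_elevated <- function(text, config = load_config()) {
  norm <- normalize_text(text)
  any(vapply(config$cholesterol_elevated_patterns,
             function(t) grepl(t, norm, fixed = TRUE), logical(1)))
}

#' Extract current interventions and drug-selection factors
#'
#' Lifestyle measures the patient already takes, lipid-lowering drug classes
#' mentioned (fibrate / statin / TCM / niacin / fish oil / other), the size
#' of a drug combination (distinct classes, reported only when >= 2), and
#' factors influencing drug selection (safety, effectiveness, economics,
#' brand, TCM preference).
#'
#' @inheritParams extract_gender
#' @return list with `lifestyle`, `drugs`, `combination_size` (`NA` if < 2),
#'   `factors`.
#' @export
extract_interventions <- function(text, config = load_config()) {
  norm <- normalize_text(text)
  drugs <- match_vocab(norm, config$drug_classes)
  list(lifestyle = match_vocab(norm, config$lifestyle_current),
       drugs = drugs,
       combination_size = if (length(drugs) >= 2L) length(drugs) else
         NA_integer_,
       factors = match_vocab(norm, config$selection_factors))
}

#' Extract the content of one response
#'
#' Lifestyle suggestions, recommended drug classes, supplement and
#' lipid-lowering-diet mentions, and the word count. `diet_control_unspecified`
#' is set only when a diet-control phrase appears with no specific dietary
#' item (reduce fats / limit carbohydrate / limit alcohol / limit oil).
#' `medication_suggested` is `TRUE` iff any drug class is recommended.
#' Word count is the whitespace-token count for English and the character
#' count for Chinese (set `language = "zh"`).
#'
#' @param response a `tg_response` (or any list with `response_id`, `text`).
#' @param config a `tg_config`.
#' @param language `"en"` or `"zh"` -- controls the word-count convention.
#' @return list mirroring the response-content record.
#' @export
extract_response_content <- function(response, config = load_config(),
                                     language = c("en", "zh")) {
  language <- match.arg(language)
  norm <- normalize_text(response$text %||% "")
  lifestyle <- match_vocab(norm, config$response_lifestyle)
  diet_specific <- c("reduce_fats", "limit_carbohydrate", "limit_alcohol",
                     "limit_oil")
  diet_phrase <- any(vapply(config$diet_control_phrases,
                            function(t) grepl(t, norm, fixed = TRUE),
                            logical(1)))
  if (diet_phrase && !any(lifestyle %in% diet_specific)) {
    lifestyle <- c(lifestyle, "diet_control_unspecified")
  }
  drugs <- match_vocab(norm, config$drug_classes)
  wc <- if (!nzchar(norm)) 0L else if (language == "zh") nchar(norm) else
    length(strsplit(norm, " ", fixed = TRUE)[[1]])
  list(response_id = response$response_id,
       lifestyle_suggestions = lifestyle,
       drugs_recommended = drugs,
       supplements = any(vapply(config$supplement_terms,
                                function(t) grepl(t, norm, fixed = TRUE),
                                logical(1))),
       lipid_lowering_diet = any(vapply(config$lipid_lowering_diet_terms,
                                        function(t) grepl(t, norm,
                                                          fixed = TRUE),
                                        logical(1))),
       medication_suggested = length(drugs) > 0L,
       word_count = as.integer(wc))
}
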