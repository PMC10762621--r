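SEVERITY_LEVELS <- c("edge", "mild_moderate", "severe")

#' Band a triglyceride value into a severity class
#'
#' Left-closed bands on the maximum TG value (mmol/L): edge elevation
#' \[1.7, 2.3), mild-to-moderate \[2.3, 5.6), severe >= 5.6. Values below
#' 1.7 are out of domain -- such posts are excluded upstream as non-topic.
#' Cut-points are configurable; the defaults follow the adult dyslipidemia
#' guideline bands the class names refer to.
#'
#' @param tg_max numeric vector of maximal TG values (mmol/L).
#' @param cutpoints list/vector with `edge`, `mild_moderate`, `severe`
#'   lower bounds (defaults 1.7, 2.3, 5.6).
#' @return character vector of class labels.
#' @export
classify_severity <- function(tg_max,
                              cutpoints = list(edge = 1.7,
                                               mild_moderate = 2.3,
                                               severe = 5.6)) {
  if (any(!is.na(tg_max) & tg_max < cutpoints$edge)) {
    stop("TG value below ", cutpoints$edge,
         " mmol/L: should have been filtered as non-topic", call. = FALSE)
  }
  ifelse(is.na(tg_max), NA_character_,
         ifelse(tg_max >= cutpoints$severe, "severe",
                ifelse(tg_max >= cutpoints$mild_moderate, "mild_moderate",
                       "edge")))
}

#' Type the hypertriglyceridemia
#'
#' `tg_plus_chol` when cholesterol co-elevation was detected, else `tg_only`.
#'
#' @param chol_elevated logical vector.
#' @return character vector.
#' @export
classify_htg_type <- function(chol_elevated) {
  ifelse(chol_elevated, "tg_plus_chol", "tg_only")
}

#' Classify the consultation demand
#'
#' Each of the 10 demand labels carries a phrase list; the assigned label is
#' the matching demand with the highest priority (lowest rank). Posts with
#' no matching phrase get `NA` (no demand identified). The tie-break is
#' deterministic and independent of phrase-list file order.
#'
#' @param text a single string (raw or normalized).
#' @param config a `tg_config`.
#' @return list with `label` and `group` (both `NA` when nothing matches).
#' @export
classify_demand <- function(text, config = load_config()) {
  norm <- normalize_text(text)
  dm <- config$demands  # already sorted by rank
  for (i in seq_len(nrow(dm))) {
    phrases <- dm$phrases[[i]]
    if (any(vapply(phrases, function(p) grepl(p, norm, fixed = TRUE),
                   logical(1)))) {
      return(list(label = dm$label[i], group = dm$group[i]))
    }
  }
  list(label = NA_character_, group = NA_character_)
}
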