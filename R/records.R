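rows_to_df <- function(rows, list_cols = character(0)) {
  # bind homogeneous row-lists into a data.frame without rbind()ing
  # one-row data.frames (quadratic); list_cols entries are stored as
  # length-1 lists wrapping the set value
  stopifnot(length(rows) > 0L)
  cols <- names(rows[[1]])
  out <- lapply(cols, function(cn) {
    if (cn %in% list_cols) {
      I(lapply(rows, function(r) r[[cn]][[1]]))
    } else {
      unlist(lapply(rows, function(r) r[[cn]]), use.names = FALSE)
    }
  })
  names(out) <- cols
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Extract patient records from kept posts
#'
#' Runs every attribute extractor over the query text of each post and
#' assembles one patient record per post: demographics (gender, proxy
#' status, relation, age, pregnancy), TG values and their maximum, severity
#' class, hypertriglyceridemia type, symptoms, secondary conditions, current
#' interventions, selection factors, and the consultation demand. Pregnancy
#' coerces an unknown gender to female. Posts without an extractable TG
#' value get `NA` severity and type.
#'
#' @param posts list of `tg_post` objects (normally the kept output of
#'   [apply_filters()]).
#' @param config a `tg_config`.
#' @return data.frame with one row per post; set-valued attributes are
#'   list-columns.
#' @export
extract_records <- function(posts, config = load_config()) {
  if (!length(posts)) return(NULL)
  cuts <- config$severity_cutpoints
  rows <- lapply(posts, function(p) {
    norm <- normalize_text(p$query_text)
    g <- extract_gender(norm, config)
    pregnant <- extract_pregnancy(norm, config)
    if (pregnant && g$gender == "unknown") g$gender <- "female"
    tg <- extract_tg_values_one(norm)
    tg_max <- if (length(tg)) max(tg) else NA_real_
    sev <- if (!is.na(tg_max) && tg_max >= cuts$edge) {
      classify_severity(tg_max, cuts)
    } else NA_character_
    chol <- extract_chol_elevated(norm, config)
    iv <- extract_interventions(norm, config)
    dem <- classify_demand(norm, config)
    list(post_id = p$post_id, platform_type = p$platform_type,
         year = p$year, gender = g$gender, is_proxy = g$is_proxy,
         relation = g$relation,
         age_years = extract_age(norm, config),
         pregnant = pregnant, tg_values = list(tg), tg_max = tg_max,
         chol_elevated = chol,
         htg_type = if (is.na(sev)) NA_character_ else
           classify_htg_type(chol),
         severity = sev,
         demand = dem$label, demand_group = dem$group,
         symptoms = list(sort(extract_symptoms(norm, config))),
         secondary = list(sort(extract_secondary(norm, config))),
         lifestyle = list(sort(iv$lifestyle)),
         drugs = list(sort(iv$drugs)),
         combination_size = iv$combination_size,
         factors = list(sort(iv$factors)))
  })
  rows_to_df(rows, list_cols = c("tg_values", "symptoms", "secondary",
                                 "lifestyle", "drugs", "factors"))
}

#' Extract response contents from posts
#'
#' Applies [extract_response_content()] to every response of every post and
#' returns one row per response with the post's platform type and the
#' responder metadata carried along.
#'
#' @inheritParams extract_records
#' @param language word-count convention, `"en"` (tokens) or `"zh"`
#'   (characters).
#' @return data.frame (or `NULL` if there are no responses).
#' @export
extract_responses <- function(posts, config = load_config(),
                              language = c("en", "zh")) {
  language <- match.arg(language)
  rows <- list()
  for (p in posts) {
    for (r in p$responses) {
      rc <- extract_response_content(r, config, language)
      rows[[length(rows) + 1L]] <- list(
        post_id = p$post_id, response_id = r$response_id,
        platform_type = p$platform_type,
        lifestyle_suggestions = list(sort(rc$lifestyle_suggestions)),
        drugs_recommended = list(sort(rc$drugs_recommended)),
        supplements = rc$supplements,
        lipid_lowering_diet = rc$lipid_lowering_diet,
        medication_suggested = rc$medication_suggested,
        word_count = rc$word_count,
        responder_title = r$responder_title %||% NA_character_,
        responder_region = r$responder_region %||% NA_character_,
        hospital_level = r$hospital_level %||% NA_character_)
    }
  }
  if (!length(rows)) return(NULL)
  rows_to_df(rows, list_cols = c("lifestyle_suggestions",
                                 "drugs_recommended"))
}
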