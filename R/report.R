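#' Percentage with half-up rounding
#'
#' `100 * numerator / denominator`, rounded *half-up* to the requested
#' number of decimals (matching how descriptive tables print percentages;
#' base `round()` rounds half-to-even).
#'
#' @param numerator,denominator counts; the denominator must be positive.
#' @param decimals digits after the decimal point.
#' @return numeric.
#' @examples
#' percent(4788, 26603, 1)   # 18.0
#' percent(7495, 13155, 2)   # 56.97
#' @export
percent <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) {
    stop("percent(): denominator must be positive", call. = FALSE)
  }
  x <- 100 * numerator / denominator
  f <- 10^decimals
  floor(x * f + 0.5 + 1e-9) / f
}

#' Severity distribution table
#'
#' Counts and within-cohort percentages of severity classes for the cohorts
#' TG-only, TG-plus-cholesterol, their pregnant subsets, and the total. The
#' pregnant rows are *subsets* of the two main cohorts, so the total counts
#' only the two non-pregnant-stratified cohorts once. Records without a
#' severity class (no TG value) are excluded.
#'
#' @param records data.frame from [extract_records()].
#' @return data.frame: `cohort`, `severity`, `count`, `percent` (percent
#'   within cohort; `NA` for empty cohorts).
#' @export
severity_distribution <- function(records) {
  sev <- factor(records$severity, levels = SEVERITY_LEVELS)
  ok <- !is.na(sev)
  cohorts <- list(
    tg_only = ok & records$htg_type == "tg_only",
    tg_plus_chol = ok & records$htg_type == "tg_plus_chol",
    pregnant_tg_only = ok & records$htg_type == "tg_only" & records$pregnant,
    pregnant_tg_plus_chol = ok & records$htg_type == "tg_plus_chol" &
      records$pregnant,
    total = ok)
  rows <- list()
  for (nm in names(cohorts)) {
    idx <- cohorts[[nm]]
    counts <- table(sev[idx])
    tot <- sum(counts)
    for (s in SEVERITY_LEVELS) {
      rows[[length(rows) + 1L]] <- list(
        cohort = nm, severity = s, count = as.integer(counts[[s]]),
        percent = if (tot > 0) percent(counts[[s]], tot, 1) else NA_real_)
    }
  }
  rows_to_df(rows)
}

#' Demand ranking table
#'
#' Demand labels sorted by descending count; ties broken by taxonomy
#' priority rank. Records without a demand are excluded.
#'
#' @param records data.frame from [extract_records()].
#' @param config a `tg_config`.
#' @return data.frame: `label`, `group`, `count`, `percent` (of records with
#'   a demand).
#' @export
demand_ranking <- function(records, config = load_config()) {
  dm <- config$demands
  counts <- vapply(dm$label, function(l) {
    sum(records$demand == l, na.rm = TRUE)
  }, integer(1))
  tot <- sum(counts)
  ord <- order(-counts, dm$rank)
  data.frame(label = dm$label[ord], group = dm$group[ord],
             count = unname(counts[ord]),
             percent = if (tot > 0) percent(unname(counts[ord]), tot, 1) else
               NA_real_,
             stringsAsFactors = FALSE)
}

demand_group_composition <- function(records, strata) {
  # percent composition of demand groups within each stratum
  ok <- !is.na(records$demand_group) & !is.na(strata)
  rows <- list()
  for (s in unique(strata[ok])) {
    idx <- ok & strata == s
    tot <- sum(idx)
    for (g in DEMAND_GROUPS) {
      cnt <- sum(records$demand_group[idx] == g)
      rows[[length(rows) + 1L]] <- list(stratum = s, group = g,
                                        count = as.integer(cnt),
                                        percent = percent(cnt, tot, 1))
    }
  }
  if (!length(rows)) return(NULL)
  rows_to_df(rows)
}

#' Demand-group composition by age
#'
#' Demand-group percentages for patients under vs at/over the split age.
#' Records with unknown age are excluded (the denominator is records with a
#' known age and an identified demand).
#'
#' @param records data.frame from [extract_records()].
#' @param split_age split point in years (default 50).
#' @return data.frame: `stratum` (`"under"`/`"over"`), `group`, `count`,
#'   `percent`.
#' @export
demand_by_age <- function(records, split_age = 50) {
  strata <- ifelse(is.na(records$age_years), NA_character_,
                   ifelse(records$age_years < split_age, "under", "over"))
  demand_group_composition(records, strata)
}

#' Demand-group composition by severity
#'
#' @param records data.frame from [extract_records()].
#' @return data.frame as in [demand_by_age()], stratified by severity class.
#' @export
demand_by_severity <- function(records) {
  demand_group_composition(records, records$severity)
}

#' Responses per query by platform type
#'
#' Total responses divided by total queries within each platform type,
#' rounded to 2 decimals. Platform types with zero queries are omitted with
#' a warning.
#'
#' @param posts list of `tg_post` objects.
#' @return named numeric vector.
#' @export
response_rates <- function(posts) {
  pt <- vapply(posts, function(p) p$platform_type, character(1))
  nresp <- vapply(posts, function(p) length(p$responses), integer(1))
  out <- c()
  for (type in PLATFORM_TYPES) {
    nq <- sum(pt == type)
    if (nq == 0L) {
      warning("no queries for platform_type ", type, "; omitted")
      next
    }
    out[type] <- round(sum(nresp[pt == type]) / nq, 2)
  }
  out
}

multiselect_frequencies <- function(responses, list_col, labels) {
  rows <- list()
  for (type in unique(responses$platform_type)) {
    idx <- responses$platform_type == type
    tot <- sum(idx)
    sets <- responses[[list_col]][idx]
    for (l in labels) {
      cnt <- sum(vapply(sets, function(s) l %in% s, logical(1)))
      rows[[length(rows) + 1L]] <- list(platform_type = type, label = l,
                                        count = as.integer(cnt),
                                        percent = percent(cnt, tot, 1))
    }
  }
  rows_to_df(rows)
}

#' Lifestyle-suggestion frequencies per platform type
#'
#' Fraction of responses carrying each lifestyle suggestion (multi-select:
#' percentages need not sum to 100).
#'
#' @param responses data.frame from [extract_responses()].
#' @param config a `tg_config`.
#' @return data.frame: `platform_type`, `label`, `count`, `percent`.
#' @export
lifestyle_suggestion_frequencies <- function(responses,
                                             config = load_config()) {
  labels <- c(names(config$response_lifestyle), "diet_control_unspecified")
  multiselect_frequencies(responses, "lifestyle_suggestions", labels)
}

#' Drug-recommendation frequencies per platform type
#'
#' Among responses that suggest medication, the fraction recommending each
#' drug class (multi-select).
#'
#' @inheritParams lifestyle_suggestion_frequencies
#' @return data.frame: `platform_type`, `label`, `count`, `percent`.
#' @export
drug_recommendation_frequencies <- function(responses,
                                            config = load_config()) {
  med <- responses[responses$medication_suggested, , drop = FALSE]
  if (!nrow(med)) return(NULL)
  multiselect_frequencies(med, "drugs_recommended",
                          names(config$drug_classes))
}

#' Medication-recommendation rate by patient severity
#'
#' For responses to posts with a TG value, the fraction whose response
#' suggests medication, stratified by the post's severity class.
#'
#' @param responses data.frame from [extract_responses()].
#' @param records data.frame from [extract_records()].
#' @return data.frame: `severity`, `n_responses`, `rate`.
#' @export
medication_rate_by_severity <- function(responses, records) {
  sev <- records$severity[match(responses$post_id, records$post_id)]
  orphan <- is.na(match(responses$post_id, records$post_id))
  if (any(orphan)) {
    stop("responses with no matching record: ",
         paste(utils::head(responses$response_id[orphan], 5),
               collapse = ", "), call. = FALSE)
  }
  rows <- lapply(SEVERITY_LEVELS, function(s) {
    idx <- !is.na(sev) & sev == s
    list(severity = s, n_responses = as.integer(sum(idx)),
         rate = if (sum(idx) > 0) {
           round(mean(responses$medication_suggested[idx]), 3)
         } else NA_real_)
  })
  rows_to_df(rows)
}

#' Annual post volume per platform type
#'
#' Counts per year over the whole 2004--2020 surveillance window; years with
#' no posts are reported as 0.
#'
#' @param posts list of `tg_post` objects.
#' @return data.frame: `year`, one column per platform type, `total`.
#' @export
annual_volume <- function(posts) {
  years <- YEAR_RANGE[1]:YEAR_RANGE[2]
  pt <- vapply(posts, function(p) p$platform_type, character(1))
  yr <- vapply(posts, function(p) p$year, integer(1))
  out <- data.frame(year = years)
  for (type in PLATFORM_TYPES) {
    out[[type]] <- vapply(years, function(y) {
      sum(yr == y & pt == type)
    }, integer(1))
  }
  out$total <- out[[PLATFORM_TYPES[1]]] + out[[PLATFORM_TYPES[2]]]
  out
}

#' Keyword frequency ranking
#'
#' Total substring-occurrence counts of every lexicon term over the given
#' texts, stoplist terms removed, sorted descending (ties alphabetical).
#'
#' @param texts character vector (raw text; normalized internally).
#' @param lexicon a `tg_lexicon`.
#' @param stoplist character vector of terms to exclude.
#' @return data.frame: `term`, `count`.
#' @export
keyword_frequency <- function(texts, lexicon = default_lexicon(),
                              stoplist = character(0)) {
  norm <- normalize_text(texts)
  terms <- setdiff(unique(unlist(lexicon$terms)), normalize_text(stoplist))
  counts <- vapply(terms, function(t) {
    sum(vapply(gregexpr(t, norm, fixed = TRUE), function(m) {
      if (m[1] == -1L) 0L else length(m)
    }, integer(1)))
  }, integer(1))
  ord <- order(-counts, terms)
  data.frame(term = terms[ord], count = unname(counts[ord]),
             stringsAsFactors = FALSE)
}

#' Assemble the full aggregate report
#'
#' @param posts kept posts (list of `tg_post`).
#' @param records data.frame from [extract_records()].
#' @param responses data.frame from [extract_responses()] (may be `NULL`).
#' @param config a `tg_config`.
#' @param lexicon a `tg_lexicon` for the keyword ranking.
#' @return list of class `tg_report` with all component tables.
#' @export
build_report <- function(posts, records, responses,
                         config = load_config(),
                         lexicon = default_lexicon()) {
  texts <- vapply(posts, function(p) p$query_text, character(1))
  has_resp <- !is.null(responses) && nrow(responses) > 0
  structure(list(
    severity_distribution = severity_distribution(records),
    demand_ranking = demand_ranking(records, config),
    demand_by_age = demand_by_age(records),
    demand_by_severity = demand_by_severity(records),
    response_rates = response_rates(posts),
    lifestyle_suggestion_frequencies = if (has_resp)
      lifestyle_suggestion_frequencies(responses, config),
    medication_rate_by_severity = if (has_resp)
      medication_rate_by_severity(responses, records),
    drug_recommendation_frequencies = if (has_resp)
      drug_recommendation_frequencies(responses, config),
    annual_volume = annual_volume(posts),
    keyword_frequency = keyword_frequency(texts, lexicon,
                                          stoplist = config$stoplist),
    mean_response_word_count = if (has_resp)
      vapply(split(responses$word_count, responses$platform_type),
             function(x) round(mean(x), 1), numeric(1))
  ), class = "tg_report")
}

#' Write a report as a directory of CSV tables
#'
#' @param report a `tg_report`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report)) {
    x <- report[[nm]]
    if (is.null(x)) next
    if (!is.data.frame(x)) {
      x <- data.frame(key = names(x), value = as.numeric(x))
    }
    utils::write.csv(x, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Run arithmetic consistency checks over printed summary counts
#'
#' Evaluates the bundled (or user-supplied) file of printed counts: each
#' check is either a `percent` (numerator/denominator must reproduce the
#' printed percentage at its printed precision), a `sum` (parts must add to
#' the printed total), or a `rate` (ratio must match within a stated
#' tolerance). Checks flagged `expect_pass: false` record printed values
#' that are internally inconsistent in the source tables.
#'
#' @param path JSON checks file; default the bundled printed counts.
#' @return data.frame: `name`, `type`, `computed`, `expected`, `pass`,
#'   `expect_pass`.
#' @export
run_consistency_checks <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "printed_counts.json",
                        package = "tglisten")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("printed-counts file not found", call. = FALSE)
  }
  checks <- jsonlite::fromJSON(path, simplifyVector = FALSE)$checks
  if (!length(checks)) {
    return(data.frame(name = character(0), type = character(0),
                      computed = numeric(0), expected = numeric(0),
                      pass = logical(0), expect_pass = logical(0)))
  }
  rows <- lapply(checks, function(ck) {
    computed <- switch(ck$type,
      percent = percent(ck$numerator, ck$denominator,
                        ck$decimals %||% 1),
      sum = sum(unlist(ck$parts)),
      rate = round(ck$numerator / ck$denominator, 2),
      stop("unknown check type: ", ck$type))
    tol <- switch(ck$type,
                  percent = 10^-(ck$decimals %||% 1) / 2 + 1e-9,
                  sum = 0,
                  rate = ck$tolerance %||% 0.02)
    list(name = ck$name, type = ck$type, computed = computed,
         expected = ck$expected,
         pass = abs(computed - ck$expected) <= tol,
         expect_pass = ck$expect_pass %||% TRUE)
  })
  rows_to_df(rows)
}
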