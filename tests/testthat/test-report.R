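cfg <- load_config()

test_that("percent rounds half-up and reproduces printed table values", {
  expect_identical(percent(4788, 26603, 1), 18.0)
  expect_identical(percent(7495, 13155, 2), 56.97)
  expect_identical(percent(2225, 9691, 1), 23.0)
  expect_identical(percent(0, 5, 1), 0.0)
  expect_identical(percent(1, 8, 1), 12.5)
  expect_identical(percent(1, 800, 1), 0.1)   # 0.125 -> half-up
  expect_error(percent(1, 0), "denominator")
})

make_pipeline_fixture <- function(n = 400, seed = 202) {
  synth <- generate_corpus(clean_config(n, seed))
  records <- extract_records(synth$posts, cfg)
  responses <- extract_responses(synth$posts, cfg)
  list(synth = synth, records = records, responses = responses)
}
fx <- make_pipeline_fixture()

test_that("severity_distribution equals a brute-force group-by recount", {
  tab <- severity_distribution(fx$records)
  r <- fx$records
  for (s in c("edge", "mild_moderate", "severe")) {
    expect_identical(
      tab$count[tab$cohort == "tg_only" & tab$severity == s],
      sum(r$htg_type == "tg_only" & r$severity == s, na.rm = TRUE))
    expect_identical(
      tab$count[tab$cohort == "pregnant_tg_plus_chol" & tab$severity == s],
      sum(r$htg_type == "tg_plus_chol" & r$severity == s & r$pregnant,
          na.rm = TRUE))
    # total row is the two main cohorts added once (pregnant rows are subsets)
    expect_identical(
      tab$count[tab$cohort == "total" & tab$severity == s],
      tab$count[tab$cohort == "tg_only" & tab$severity == s] +
        tab$count[tab$cohort == "tg_plus_chol" & tab$severity == s])
  }
  # conservation: total equals records with >= 1 TG value
  expect_identical(sum(tab$count[tab$cohort == "total"]),
                   sum(!is.na(r$severity)))
  # closure: cohort percents sum to 100 +- 0.2
  for (co in unique(tab$cohort)) {
    p <- tab$percent[tab$cohort == co]
    if (all(is.na(p))) next
    expect_lt(abs(sum(p) - 100), 0.2)
  }
  # empty input gives an all-zero table
  empty <- severity_distribution(fx$records[0, ])
  expect_true(all(empty$count == 0L))
  expect_true(all(is.na(empty$percent)))
})

test_that("demand_ranking counts match table() and ties use taxonomy order", {
  rk <- demand_ranking(fx$records, cfg)
  oracle <- table(fx$records$demand)
  for (i in seq_len(nrow(rk))) {
    cnt <- if (rk$label[i] %in% names(oracle)) {
      as.integer(oracle[[rk$label[i]]])
    } else 0L
    expect_identical(rk$count[i], cnt)
  }
  expect_true(all(diff(rk$count) <= 0))

  # tie: equal counts resolved by priority rank
  two <- fx$records[1:2, ]
  two$demand <- c("disease_concepts", "drug_selection")
  rk2 <- demand_ranking(two, cfg)
  expect_identical(rk2$label[1:2], c("drug_selection", "disease_concepts"))
})

test_that("demand stratifications exclude unknowns and close to 100", {
  by_age <- demand_by_age(fx$records)
  for (s in unique(by_age$stratum)) {
    expect_lt(abs(sum(by_age$percent[by_age$stratum == s]) - 100), 0.2)
  }
  known <- !is.na(fx$records$age_years) & !is.na(fx$records$demand_group)
  expect_identical(sum(by_age$count), sum(known))

  by_sev <- demand_by_severity(fx$records)
  expect_identical(sum(by_sev$count),
                   sum(!is.na(fx$records$severity) &
                         !is.na(fx$records$demand_group)))
})

test_that("response_rates divides responses by queries per platform type", {
  one_each <- lapply(1:6, function(i) {
    make_post(paste0("p", i), "t",
              type = if (i %% 2) "qa_search" else "online_consultation",
              responses = list(raw_response(paste0("r", i), "text")))
  })
  expect_identical(response_rates(one_each),
                   c(qa_search = 1, online_consultation = 1))
  # brute-force oracle on the synthetic fixture
  rates <- response_rates(fx$synth$posts)
  pt <- vapply(fx$synth$posts, function(p) p$platform_type, character(1))
  nr <- vapply(fx$synth$posts, function(p) length(p$responses), integer(1))
  for (type in names(rates)) {
    expect_identical(rates[[type]],
                     round(sum(nr[pt == type]) / sum(pt == type), 2))
  }
  expect_warning(response_rates(one_each[c(1, 3, 5)]), "omitted")
})

test_that("annual_volume matches a histogram oracle and conserves counts", {
  av <- annual_volume(fx$synth$posts)
  expect_identical(av$year, 2004:2020)
  expect_identical(sum(av$total), length(fx$synth$posts))
  yr <- vapply(fx$synth$posts, function(p) p$year, integer(1))
  oracle <- as.integer(table(factor(yr, levels = 2004:2020)))
  expect_identical(av$total, oracle)
  # empty corpus: 17 zeros
  empty <- annual_volume(list())
  expect_identical(empty$total, rep(0L, 17))
})

test_that("keyword_frequency matches a brute-force occurrence count", {
  texts <- c("treatment treatment diet", "diet and food", "tg tg tg")
  lex <- default_lexicon("en")
  kf <- keyword_frequency(texts, lex, stoplist = character(0))
  expect_identical(kf$count[kf$term == "diet"], 2L)
  expect_identical(kf$count[kf$term == "food"], 1L)
  expect_identical(kf$count[kf$term == "tg"], 3L)
  expect_true(all(diff(kf$count) <= 0))
  # stoplist removes terms
  kf2 <- keyword_frequency(texts, lex, stoplist = "tg")
  expect_false("tg" %in% kf2$term)
})

test_that("multi-select response tables match brute-force recounts", {
  lf <- lifestyle_suggestion_frequencies(fx$responses, cfg)
  for (type in unique(fx$responses$platform_type)) {
    idx <- fx$responses$platform_type == type
    for (lab in c("reduce_fats", "exercise", "diet_control_unspecified")) {
      oracle <- sum(vapply(fx$responses$lifestyle_suggestions[idx],
                           function(s) lab %in% s, logical(1)))
      expect_identical(lf$count[lf$platform_type == type & lf$label == lab],
                       oracle)
    }
  }
  med <- medication_rate_by_severity(fx$responses, fx$records)
  sev <- fx$records$severity[match(fx$responses$post_id,
                                   fx$records$post_id)]
  for (s in c("edge", "mild_moderate", "severe")) {
    idx <- !is.na(sev) & sev == s
    expect_identical(
      med$rate[med$severity == s],
      round(mean(fx$responses$medication_suggested[idx]), 3))
  }
  orphan <- fx$responses[1, , drop = FALSE]
  orphan$post_id <- "nonexistent"
  expect_error(medication_rate_by_severity(orphan, fx$records),
               "no matching record")
})

test_that("consistency checks verify printed counts and flag discrepancies", {
  res <- run_consistency_checks()
  expect_gt(nrow(res), 40)
  # every check behaves as expected: consistent printed values pass, the
  # two known printed discrepancies fail
  expect_identical(res$pass, res$expect_pass)
  expect_identical(sum(!res$expect_pass), 2L)

  # perturbing one count by 1 makes exactly that check fail
  raw <- jsonlite::fromJSON(system.file("extdata", "printed_counts.json",
                                        package = "tglisten"),
                            simplifyVector = FALSE)
  i <- which(vapply(raw$checks, function(ck) ck$name, character(1)) ==
               "gender_total_sum")
  raw$checks[[i]]$parts[[1]] <- raw$checks[[i]]$parts[[1]] + 1L
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(raw, f, auto_unbox = TRUE)
  res2 <- run_consistency_checks(f)
  expect_false(res2$pass[res2$name == "gender_total_sum"])
  expect_identical(res$pass[res$name != "gender_total_sum"],
                   res2$pass[res2$name != "gender_total_sum"])
  expect_error(run_consistency_checks("/nonexistent.json"), "not found")
})
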