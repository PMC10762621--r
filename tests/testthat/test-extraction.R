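cfg <- load_config()

test_that("extract_gender handles proxy, direct and absent cues", {
  g <- extract_gender("my father's TG is 5.8", cfg)
  expect_identical(g, list(gender = "male", is_proxy = TRUE,
                           relation = "father"))
  g <- extract_gender("I am a 30 year old woman", cfg)
  expect_identical(g[c("gender", "is_proxy")],
                   list(gender = "female", is_proxy = FALSE))
  g <- extract_gender("my wife has high TG", cfg)
  expect_identical(g$gender, "female")
  g <- extract_gender("my parent is unwell", cfg)
  expect_identical(g[c("gender", "is_proxy")],
                   list(gender = "unknown", is_proxy = TRUE))
  expect_identical(extract_gender("TG question", cfg)$gender, "unknown")
})

test_that("extract_age covers direct, indirect and absent patterns", {
  expect_identical(extract_age("my 67 year old mother", cfg), 67)
  expect_identical(extract_age("i am a 45-year-old man", cfg), 45)
  expect_identical(extract_age("patient aged 52 with high tg", cfg), 52)
  expect_identical(extract_age("i am in my twenties", cfg), 25)
  expect_true(is.na(extract_age("no age cue here", cfg)))
  # gestation weeks are not an age
  expect_true(is.na(extract_age("28 weeks pregnant", cfg)))
})

test_that("extract_tg_values parses units, multiples and adjacency", {
  expect_equal(extract_tg_values("triglyceride 2.4 mmol/L"), 2.4)
  expect_equal(extract_tg_values("TG 150 mg/dL"), 150 / 88.57)
  expect_equal(extract_tg_values("TG was 1.5 then 2.4 mmol/L"), c(1.5, 2.4))
  expect_identical(extract_tg_values("no numbers at all"), numeric(0))
  # numbers not adjacent to a TG term are ignored
  expect_identical(extract_tg_values("i am 45 years old"), numeric(0))
  # ages and gestation weeks next to a TG term are skipped
  expect_equal(extract_tg_values("tg of my 45 year old father is 3.2"), 3.2)
  # values in a later sentence are not attributed to the term
  expect_identical(extract_tg_values("my tg is high. i walk 5 km"),
                   numeric(0))
})

test_that("mmol/L and mg/dL forms of the same quantity agree within 0.01", {
  set.seed(5)
  for (v in round(runif(50, 1.7, 20), 1)) {
    a <- extract_tg_values(sprintf("tg %.1f mmol/l", v))
    b <- extract_tg_values(sprintf("tg %.0f mg/dl", v * 88.57))
    expect_equal(a, v)
    expect_lt(abs(b - v), 0.01)
  }
})

test_that("pregnancy, symptoms and secondary conditions extract by vocabulary", {
  expect_true(extract_pregnancy("28 weeks pregnant, TG 3.9", cfg))
  expect_false(extract_pregnancy("no cue here", cfg))

  expect_identical(extract_symptoms("dizzy all day", cfg), "head")
  expect_setequal(extract_symptoms("chest pain and headache", cfg),
                  c("head", "chest"))
  expect_length(extract_symptoms("nothing hurts", cfg), 0L)

  expect_identical(extract_secondary("after my myocardial infarction", cfg),
                   "ascvd_cardiac")
  expect_identical(extract_secondary("cerebral infarction last year", cfg),
                   "ascvd_cerebral")
  expect_length(extract_secondary("healthy otherwise", cfg), 0L)
})

test_that("extract_interventions maps drugs, combinations and factors", {
  iv <- extract_interventions("taking fenofibrate and xuezhikang", cfg)
  expect_setequal(iv$drugs, c("fibrate", "tcm"))
  expect_identical(iv$combination_size, 2L)

  iv <- extract_interventions("is atorvastatin safe long term?", cfg)
  expect_identical(iv$drugs, "statin")
  expect_identical(iv$factors, "safety")
  expect_true(is.na(iv$combination_size))

  iv <- extract_interventions("no mention of anything", cfg)
  expect_length(iv$drugs, 0L)
  expect_length(iv$lifestyle, 0L)
  expect_length(iv$factors, 0L)
})

test_that("extract_response_content applies suggestion vocabularies", {
  rc <- extract_response_content(
    raw_response("r1", "reduce fatty food and exercise more"), cfg)
  expect_setequal(rc$lifestyle_suggestions, c("reduce_fats", "exercise"))
  expect_false(rc$medication_suggested)

  # diet-control phrase with no specific item
  rc <- extract_response_content(raw_response("r2", "control your diet"),
                                 cfg)
  expect_identical(rc$lifestyle_suggestions, "diet_control_unspecified")
  # ... but not when a specific item accompanies it
  rc <- extract_response_content(
    raw_response("r3", "control your diet and limit alcohol"), cfg)
  expect_false("diet_control_unspecified" %in% rc$lifestyle_suggestions)

  rc <- extract_response_content(raw_response("r4", ""), cfg)
  expect_length(rc$lifestyle_suggestions, 0L)
  expect_identical(rc$word_count, 0L)

  rc <- extract_response_content(
    raw_response("r5", "i recommend fenofibrate and fish oil"), cfg)
  expect_setequal(rc$drugs_recommended, c("fibrate", "fish_oil"))
  expect_true(rc$medication_suggested)
  expect_identical(rc$word_count, 6L)
})

test_that("extractors are pure: identical text gives identical output", {
  texts <- vapply(fixture_corpus_50()[1:10], function(p) p$query_text,
                  character(1))
  for (tx in texts) {
    expect_identical(extract_gender(tx, cfg), extract_gender(tx, cfg))
    expect_identical(extract_tg_values(tx), extract_tg_values(tx))
    expect_identical(classify_demand(tx, cfg), classify_demand(tx, cfg))
  }
})
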