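cfg <- load_config()

test_that("drop_duplicates keeps first occurrences only", {
  posts <- lapply(c("a", "b", "a", "c", "b"), function(id) {
    make_post(id, "my tg is 2.4 mmol/l")
  })
  out <- drop_duplicates(posts)
  expect_identical(vapply(out$kept, function(p) p$post_id, character(1)),
                   c("a", "b", "c"))
  expect_identical(sum(out$decisions$verdict == "drop"), 2L)
  expect_true(all(out$decisions$rule_fired[out$decisions$verdict == "drop"]
                  == "duplicate"))

  unique_posts <- lapply(letters[1:5], function(id) make_post(id, "t"))
  expect_identical(sum(drop_duplicates(unique_posts)$decisions$verdict ==
                         "drop"), 0L)
})

test_that("drop_duplicates matches a set-based oracle on random id streams", {
  set.seed(99)
  for (rep in 1:20) {
    ids <- sample(sprintf("id%02d", 1:30), 50, replace = TRUE)
    posts <- lapply(seq_along(ids), function(i) make_post(ids[i], "t"))
    kept_ids <- vapply(drop_duplicates(posts)$kept,
                       function(p) p$post_id, character(1))
    expect_identical(kept_ids, unique(ids))
  }
})

test_that("advertisement and popular-science rules match the hand labels", {
  cases <- read.delim(test_path("fixtures", "filter_cases.csv"),
                      sep = "|", stringsAsFactors = FALSE)
  expect_identical(nrow(cases), 40L)
  for (i in seq_len(nrow(cases))) {
    p <- make_post(sprintf("c%02d", i), cases$text[i])
    expect_identical(is_advertisement(p, cfg), cases$is_ad[i],
                     info = paste("ad:", cases$text[i]))
    expect_identical(is_popular_science(p, cfg), cases$is_science[i],
                     info = paste("science:", cases$text[i]))
  }
})

test_that("non-topic rule fires only when all TG values are below 1.7", {
  expect_true(is_non_topic(make_post("a", "TG 1.5 mmol/L, is this fine?")))
  expect_false(is_non_topic(make_post("b", "TG was 1.5 last year, now 2.4")))
  expect_false(is_non_topic(make_post("c", "no lab values mentioned here")))
  expect_false(is_non_topic(make_post("d", "my triglyceride is 1.7 mmol/l")))
})

test_that("apply_filters: precedence, completeness, idempotence", {
  synth <- generate_corpus(generator_config(n_posts = 150, seed = 21))
  out <- apply_filters(synth$posts, cfg)
  # completeness: one decision per input post
  expect_identical(nrow(out$decisions), length(synth$posts))
  expect_identical(length(out$kept) +
                     sum(out$decisions$verdict == "drop"),
                   length(synth$posts))
  expect_true(all(xor(out$decisions$verdict == "keep",
                      out$decisions$rule_fired != "none")))
  # idempotence on kept output
  again <- apply_filters(out$kept, cfg)
  expect_identical(again$kept, out$kept)
  expect_true(all(again$decisions$verdict == "keep"))
  # clean corpus: everything kept
  clean <- generate_corpus(clean_config(80, seed = 3))
  expect_length(apply_filters(clean$posts, cfg)$kept, 80L)
})

test_that("permuting input order changes no verdict except duplicate choice", {
  synth <- generate_corpus(generator_config(n_posts = 80, seed = 13))
  out1 <- apply_filters(synth$posts, cfg)
  set.seed(7)
  perm <- sample(seq_along(synth$posts))
  out2 <- apply_filters(synth$posts[perm], cfg)
  d1 <- out1$decisions
  d2 <- out2$decisions
  # non-duplicate verdicts are order-independent (duplicates: first-in wins,
  # so which copy survives may change but the count of drops cannot)
  nd1 <- d1[d1$rule_fired != "duplicate", ]
  nd2 <- d2[d2$rule_fired != "duplicate", ]
  expect_identical(sum(d1$rule_fired == "duplicate"),
                   sum(d2$rule_fired == "duplicate"))
  m <- match(nd1$post_id, nd2$post_id)
  dup_ids <- d1$post_id[duplicated(d1$post_id)]
  same <- !(nd1$post_id %in% dup_ids)
  expect_identical(nd1$rule_fired[same], nd2$rule_fired[m][same])
})

test_that("low-TG contaminants are exactly the posts the non-topic rule flags", {
  synth <- generate_corpus(generator_config(
    n_posts = 200, seed = 31,
    contamination = list(duplicate_rate = 0, ad_rate = 0,
                         science_rate = 0, low_tg_rate = 0.1)))
  flagged <- vapply(synth$posts, is_non_topic, logical(1), config = cfg)
  expect_identical(flagged, synth$truth$contaminant_kind == "non_topic")
})

test_that("stand-in classifier separates ads from patient posts", {
  synth <- generate_corpus(generator_config(
    n_posts = 150, seed = 77,
    contamination = list(duplicate_rate = 0, ad_rate = 1.0,
                         science_rate = 0, low_tg_rate = 0)))
  texts <- vapply(synth$posts, function(p) p$query_text, character(1))
  labels <- ifelse(synth$truth$is_contaminant, "ad", "post")
  train <- 1:200
  test <- 201:300
  clf <- train_stand_in_classifier(texts[train], labels[train])
  pred <- classify_text(clf, texts[test])
  expect_gte(mean(pred == labels[test]), 0.9)
  # training items reproduce their labels on separable data
  expect_identical(classify_text(clf, texts[train]), labels[train])
  # retraining is deterministic
  clf2 <- train_stand_in_classifier(texts[train], labels[train])
  expect_identical(classify_text(clf2, texts[test]), pred)
  expect_error(train_stand_in_classifier(c("a", "b"), c("x", "x")),
               "two labels")
})
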