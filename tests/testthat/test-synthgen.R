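test_that("generator config validates probabilities and mixtures", {
  expect_error(generator_config(0), "n_posts")
  expect_error(generator_config(10, platform_mix = 1.5), "probability")
  expect_error(generator_config(10, severity_mix = c(edge = 0.5,
                                                     mild_moderate = 0.4,
                                                     severe = 0.4)),
               "sum to 1")
  expect_error(generator_config(10, template_language = "zh"),
               "template family")
})

test_that("zero contamination yields exactly n clean posts with truth rows", {
  synth <- generate_corpus(clean_config(100, seed = 7))
  expect_length(synth$posts, 100L)
  expect_identical(nrow(synth$truth), 100L)
  expect_false(any(synth$truth$is_contaminant))
  expect_true(all(synth$truth$contaminant_kind == "none"))
  # one truth row per post, aligned by position
  expect_identical(synth$truth$post_id,
                   vapply(synth$posts, function(p) p$post_id, character(1)))
})

test_that("duplicate contaminants reuse earlier post ids", {
  synth <- generate_corpus(generator_config(
    n_posts = 10, seed = 3,
    contamination = list(duplicate_rate = 1.0, ad_rate = 0,
                         science_rate = 0, low_tg_rate = 0)))
  ids <- vapply(synth$posts, function(p) p$post_id, character(1))
  dup_ids <- ids[duplicated(ids)]
  expect_length(dup_ids, 10L)
  clean_ids <- synth$truth$post_id[!synth$truth$is_contaminant]
  expect_true(all(dup_ids %in% clean_ids))
  # every duplicate appears after its source (first occurrence is clean)
  firsts <- match(unique(ids), ids)
  expect_false(any(synth$truth$is_contaminant[firsts]))
})

test_that("contaminant truth rows carry no patient labels", {
  synth <- generate_corpus(generator_config(n_posts = 60, seed = 9))
  contam <- synth$truth[synth$truth$is_contaminant, ]
  expect_gt(nrow(contam), 0L)
  expect_true(all(is.na(contam$gender)))
  expect_true(all(is.na(contam$severity)))
  expect_true(all(vapply(contam$tg_values, length, integer(1)) == 0L))
})

test_that("identical config and seed give byte-identical corpus and truth", {
  cfg <- generator_config(n_posts = 60, seed = 123)
  s1 <- generate_corpus(cfg)
  s2 <- generate_corpus(cfg)
  expect_identical(s1$posts, s2$posts)
  expect_identical(s1$truth, s2$truth)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(s1$posts, f1)
  write_corpus(s2$posts, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # a different seed changes the corpus
  s3 <- generate_corpus(generator_config(n_posts = 60, seed = 124))
  expect_false(identical(s1$posts, s3$posts))
  # the generator does not disturb the session RNG stream
  set.seed(42); a <- runif(1)
  set.seed(42); invisible(generate_corpus(cfg)); b <- runif(1)
  expect_identical(a, b)
})

test_that("clean TG values respect their severity band", {
  synth <- generate_corpus(clean_config(400, seed = 15))
  tr <- synth$truth
  mx <- vapply(tr$tg_values, max, numeric(1))
  lo <- c(edge = 1.7, mild_moderate = 2.3, severe = 5.6)
  hi <- c(edge = 2.3, mild_moderate = 5.6, severe = 20.0)
  expect_true(all(mx >= lo[tr$severity] & mx < hi[tr$severity]))
  # pregnancy only among females
  expect_true(all(tr$gender[tr$pregnant] == "female"))
})

test_that("truth sidecar writes one JSONL record per post", {
  synth <- generate_corpus(generator_config(n_posts = 20, seed = 2))
  f <- withr::local_tempfile(fileext = ".jsonl")
  n <- write_truth(synth, f)
  expect_identical(n, nrow(synth$truth))
  expect_identical(length(readLines(f)), nrow(synth$truth))
})

test_that("recovery_report is exact when pipeline output is the truth", {
  synth <- generate_corpus(clean_config(50, seed = 44))
  records <- extract_records(synth$posts)
  rr <- recovery_report(synth, records)
  expect_true(all(rr$attribute_accuracy$accuracy == 1))
  expect_true(all(rr$proportion_error$abs_error == 0))
  # join error on unknown post ids
  bad <- records
  bad$post_id[1] <- "martian"
  expect_error(recovery_report(synth, bad), "absent from ground truth")
})
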