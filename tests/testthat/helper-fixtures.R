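# shared fixtures: built in code, no binary data

make_post <- function(id, text, type = "qa_search", year = 2015,
                      platform = "baidu_zhidao", responses = list()) {
  raw_post(id, platform, type, year, text, responses)
}

# a deterministic 50-post mixed fixture for matcher oracles: clean synthetic
# posts plus hand-written odds and ends
fixture_corpus_50 <- function() {
  synth <- generate_corpus(generator_config(
    n_posts = 44, seed = 404,
    contamination = list(duplicate_rate = 0, ad_rate = 0,
                         science_rate = 0, low_tg_rate = 0)))
  extra <- list(
    make_post("x1", "what is a healthy breakfast"),
    make_post("x2", "my TG is 2.5 and I eat a lot of food"),
    make_post("x3", "fenofibrate dosage for blood lipid control"),
    make_post("x4", "hypertriglyceridemia and diet advice please"),
    make_post("x5", "weather is nice today"),
    make_post("x6", "bezafibrate or statins for dyslipidemia?"))
  c(synth$posts, extra)
}

random_ascii <- function(n, min_len = 0, max_len = 40) {
  chars <- c(letters, LETTERS, 0:9, " ", " ", "\t", ".", ",", "/", "-")
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    paste(sample(chars, len, replace = TRUE), collapse = "")
  }, character(1))
}

clean_config <- function(n, seed) {
  generator_config(n_posts = n, seed = seed,
                   contamination = list(duplicate_rate = 0, ad_rate = 0,
                                        science_rate = 0, low_tg_rate = 0))
}
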