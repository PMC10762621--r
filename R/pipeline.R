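#' Run the full listening pipeline over a corpus
#'
#' Retrieval (keyword strategy), exclusion filtering (duplicate /
#' advertisement / popular-science / non-topic), attribute extraction,
#' severity and demand classification, and aggregation into the report
#' tables.
#'
#' @param posts list of `tg_post` objects (e.g. from [read_corpus()] or
#'   [generate_corpus()]).
#' @param config a `tg_config`.
#' @param lexicon a `tg_lexicon`.
#' @param strategy a `tg_strategy`.
#' @return list of class `tg_pipeline`: `retrieved` (retrieval result),
#'   `decisions` (filter decisions over the retrieved posts), `kept`
#'   (surviving posts), `records`, `responses`, `report`.
#' @export
run_pipeline <- function(posts, config = load_config(),
                         lexicon = default_lexicon(),
                         strategy = default_strategy()) {
  ret <- retrieve(posts, strategy, lexicon)
  flt <- apply_filters(ret$kept, config)
  records <- extract_records(flt$kept, config)
  responses <- extract_responses(flt$kept, config,
                                 language = lexicon$language)
  report <- build_report(flt$kept, records, responses, config, lexicon)
  structure(list(retrieved = ret, decisions = flt$decisions,
                 kept = flt$kept, records = records, responses = responses,
                 report = report),
            class = "tg_pipeline")
}
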