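DEMAND_GROUPS <- c("how_to_intervene", "drug_intervention",
                   "disease_cognition", "lifestyle_intervention")

#' Load the pipeline configuration
#'
#' The configuration bundles every editable vocabulary the rule-based stages
#' use: severity cut-points (mmol/L), the 10-label demand taxonomy with its
#' phrase lists and priority ranks, the relation-to-gender table for proxy
#' consultations, indirect age phrases, symptom / secondary-condition /
#' lifestyle / drug-class / selection-factor vocabularies, response-suggestion
#' vocabularies, and the contamination marker lists (link tokens, promotion
#' markers, popular-science markers, personal-illness patterns).
#'
#' @param path JSON config file; defaults to the bundled English config.
#' @return list of class `tg_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "config_en.json", package = "tglisten",
                        mustWork = TRUE)
  }
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg$demands <- as.data.frame(cfg$demands)
  stopifnot(nrow(cfg$demands) == 10L,
            all(cfg$demands$group %in% DEMAND_GROUPS),
            !anyDuplicated(cfg$demands$rank))
  cfg$demands <- cfg$demands[order(cfg$demands$rank), ]
  cuts <- cfg$severity_cutpoints
  stopifnot(cuts$edge < cuts$mild_moderate, cuts$mild_moderate < cuts$severe)
  structure(cfg, class = "tg_config")
}

#' Demand taxonomy
#'
#' The 10 consultation-demand labels in priority order (rank 1 highest) with
#' their group assignment: `how_to_intervene` (1 label), `drug_intervention`
#' (2), `disease_cognition` (4 -- the perception/cognition/recognition
#' variants are unified), `lifestyle_intervention` (3).
#'
#' @param config a `tg_config`; defaults to the bundled one.
#' @return data.frame with columns `label`, `rank`, `group`, `phrases`
#'   (list-column).
#' @export
demand_taxonomy <- function(config = load_config()) {
  config$demands[, c("label", "rank", "group", "phrases")]
}
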