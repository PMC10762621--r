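QA_PLATFORMS <- c("baidu_zhidao", "sogou_wenwen", "360_qa", "iask",
                  "baidu_tieba", "zhihu")
CONSULT_PLATFORMS <- c("120_ask", "xunyiwenyao", "99_health", "wedoctor",
                       "qiuyi", "family_doctor", "dingxiang", "haodaifu",
                       "39_ask", "feihua", "chinakang", "99_ask_doctor",
                       "chunyu", "baixing_wen_yisheng")
# post volume rises to a 2017 peak then declines (2004..2020)
YEAR_WEIGHTS <- c(1, 2, 3, 4, 5, 6, 8, 10, 12, 14, 17, 20, 24, 28, 22, 16, 12)

DEMAND_VOLUMES <- c(how_to_treat = 14194, drug_selection = 9782,
                    disease_concepts = 6281, lifestyle_precautions = 3789,
                    disease_causes = 3477, medication = 3042,
                    dietary_control = 2551, lipid_lowering_foods = 1994,
                    disease_impact = 1973, diagnosis_treatment_criteria = 1814)

TITLE_PROBS <- c(attending = 0.371, resident = 0.215, associate_chief = 0.181,
                 chief = 0.122, nurse = 0.108, other = 0.003)
REGIONS <- c("shandong", "hebei", "liaoning", "henan", "jiangxi", "jilin",
             "guangdong", "sichuan")
REGION_WEIGHTS <- c(4, 3.5, 3.5, 2.5, 2.5, 2.5, 1.5, 1.5)

check_prob <- function(x, nm) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("generator config: ", nm, " must be a probability in [0, 1]",
         call. = FALSE)
  }
}
check_mix <- function(x, nm) {
  check_prob(x, nm)
  if (abs(sum(x) - 1) > 1e-9) {
    stop("generator config: ", nm, " must sum to 1 (got ", sum(x), ")",
         call. = FALSE)
  }
}

#' Build a synthetic-corpus generator configuration
#'
#' Defaults are the study-population marginals the analysis assumes: a
#' 53/47 Q&A-vs-consultation platform split, 43% female patients, proxy
#' consultation rates of 27.6% (female) and 20.8% (male), a 15.8% pregnancy
#' rate among females, TG severity shares 19.3/52.3/28.4 (edge /
#' mild-to-moderate / severe), a 26.7% cholesterol co-elevation rate, the
#' 10-demand mix proportional to the demand-ranking volumes, drug /
#' lifestyle / factor mention rates, mean response counts 1.34 (Q&A) and
#' 1.88 (consultation), and per-severity medication-recommendation rates
#' 66.2/77.8/88.1%. Contamination rates are expected contaminants per clean
#' post (contaminants are generated in addition to `n_posts`).
#'
#' @param n_posts number of clean posts (>= 1).
#' @param seed integer RNG seed; identical `(config, seed)` gives a
#'   byte-identical corpus.
#' @param platform_mix probability a post is on a Q&A search platform.
#' @param gender_mix probability the patient is female.
#' @param proxy_rate_female,proxy_rate_male probability the post is a proxy
#'   consultation, by patient gender.
#' @param pregnancy_rate probability of pregnancy among female patients.
#' @param age_mix mixture over age bands `le20`, `mid21_60`, `gt60`.
#' @param severity_mix mixture over `edge`, `mild_moderate`, `severe`.
#' @param chol_co_elevation_rate probability of cholesterol co-elevation.
#' @param contamination list with `duplicate_rate`, `ad_rate`,
#'   `science_rate`, `low_tg_rate`.
#' @param demand_mix named mixture over the 10 demand labels (taxonomy
#'   order); default proportional to the demand-ranking volumes.
#' @param symptom_rate probability a post mentions symptoms.
#' @param secondary_rates named rates for secondary conditions.
#' @param lifestyle_mention_rate,drug_mention_rate,factor_rate probabilities
#'   a post mentions current lifestyle measures, drugs, selection factors.
#' @param combo_rate probability a drug mention is a combination;
#'   `combo3_share` is the share of 3-drug combinations among combinations.
#' @param response_count_mean named means (`qa_search`,
#'   `online_consultation`) of the Poisson response-count distribution.
#' @param medication_rate_by_severity named per-severity probabilities that
#'   a response recommends medication.
#' @param response_lifestyle_rates named per-suggestion probabilities.
#' @param response_drug_rates named per-class recommendation probabilities
#'   (multi-select, conditional on medication being suggested).
#' @param diet_phrase_rate probability a response carries an unspecific
#'   diet-control phrase.
#' @param supplement_rate,lld_rate named (`qa_search`,
#'   `online_consultation`) rates for supplement and lipid-lowering-diet
#'   mentions.
#' @param multi_tg_rate probability a post reports two TG values.
#' @param mgdl_rate probability the TG value is written in mg/dL.
#' @param indirect_age_rate probability a self post states age indirectly.
#' @param template_language `"en"` (the `"zh"` template family is not
#'   implemented; the Chinese lexicon is bundled for matching real text).
#' @return list of class `tg_generator_config`.
#' @export
generator_config <- function(n_posts,
                             seed = 1L,
                             platform_mix = 0.53,
                             gender_mix = 0.43,
                             proxy_rate_female = 0.276,
                             proxy_rate_male = 0.208,
                             pregnancy_rate = 0.158,
                             age_mix = c(le20 = 0.05, mid21_60 = 0.87,
                                         gt60 = 0.08),
                             severity_mix = c(edge = 0.193,
                                              mild_moderate = 0.523,
                                              severe = 0.284),
                             chol_co_elevation_rate = 0.267,
                             contamination = list(duplicate_rate = 0.05,
                                                  ad_rate = 0.05,
                                                  science_rate = 0.05,
                                                  low_tg_rate = 0.05),
                             demand_mix = DEMAND_VOLUMES / sum(DEMAND_VOLUMES),
                             symptom_rate = 0.127,
                             secondary_rates = c(ascvd_cardiac = 0.013,
                                                 ascvd_cerebral = 0.006,
                                                 pancreatitis = 0.006),
                             lifestyle_mention_rate = 0.018,
                             drug_mention_rate = 0.097,
                             factor_rate = 0.039,
                             combo_rate = 0.041,
                             combo3_share = 0.142,
                             response_count_mean = c(qa_search = 1.34,
                                                     online_consultation = 1.88),
                             medication_rate_by_severity = c(edge = 0.662,
                                                             mild_moderate = 0.778,
                                                             severe = 0.881),
                             response_lifestyle_rates = c(reduce_fats = 0.772,
                                                          exercise = 0.63,
                                                          smoking_cessation = 0.10,
                                                          weight_control = 0.12,
                                                          limit_carbohydrate = 0.14,
                                                          limit_alcohol = 0.20,
                                                          limit_oil = 0.15),
                             response_drug_rates = c(statin = 0.561,
                                                     fibrate = 0.517,
                                                     tcm = 0.128,
                                                     niacin = 0.05,
                                                     fish_oil = 0.05,
                                                     other = 0.02),
                             diet_phrase_rate = 0.124,
                             supplement_rate = c(qa_search = 0.031,
                                                 online_consultation = 0.016),
                             lld_rate = c(qa_search = 0.137,
                                          online_consultation = 0.075),
                             multi_tg_rate = 0.15,
                             mgdl_rate = 0.10,
                             indirect_age_rate = 0.10,
                             template_language = "en") {
  if (!is.numeric(n_posts) || length(n_posts) != 1L || n_posts < 1) {
    stop("n_posts must be >= 1", call. = FALSE)
  }
  if (template_language != "en") {
    stop("only the 'en' template family is implemented", call. = FALSE)
  }
  check_prob(c(platform_mix, gender_mix, proxy_rate_female, proxy_rate_male,
               pregnancy_rate, chol_co_elevation_rate, symptom_rate,
               lifestyle_mention_rate, drug_mention_rate, factor_rate,
               combo_rate, combo3_share, diet_phrase_rate, multi_tg_rate,
               mgdl_rate, indirect_age_rate), "scalar rates")
  check_prob(unlist(contamination), "contamination rates")
  check_prob(secondary_rates, "secondary_rates")
  check_prob(medication_rate_by_severity, "medication_rate_by_severity")
  check_prob(response_lifestyle_rates, "response_lifestyle_rates")
  check_prob(response_drug_rates, "response_drug_rates")
  check_prob(supplement_rate, "supplement_rate")
  check_prob(lld_rate, "lld_rate")
  check_mix(age_mix, "age_mix")
  check_mix(severity_mix, "severity_mix")
  check_mix(demand_mix, "demand_mix")
  stopifnot(all(response_count_mean > 0))
  structure(as.list(environment()), class = "tg_generator_config")
}

tg_grid <- function(lo, hi) round(seq(lo, hi, by = 0.1), 1)

demand_sentence <- function(label, phrase) {
  if (label == "lipid_lowering_foods") paste0(phrase, " blood lipids?")
  else paste0(phrase, "?")
}

LIFESTYLE_SENT <- c(smoking_cessation = "i quit smoking last year",
                    weight_control = "i am trying to lose weight",
                    exercise = "i exercise three times a week",
                    limit_carbohydrate = "i limit carbohydrate intake",
                    limit_alcohol = "i limit alcohol now",
                    limit_oil = "i cook with less oil",
                    diet_control = "i keep a strict diet")
DRUG_NAMES <- c(fibrate = "fenofibrate", statin = "atorvastatin",
                tcm = "xuezhikang", niacin = "niacin", fish_oil = "fish oil",
                other = "ezetimibe")
FACTOR_SENT <- c(safety = "is it safe to take for a long time?",
                 effectiveness = "i wonder how effective it is.",
                 economics = "it is quite expensive for me.",
                 brand = "which brand is better?",
                 tcm_preference = "i prefer traditional chinese medicine.")
SYMPTOM_TERM <- list(head = c("dizziness", "headache"),
                     chest = c("chest tightness", "chest pain", "palpitation",
                               "shortness of breath"),
                     other = c("fatigue", "blurred vision", "numbness"))
SECONDARY_SENT <- c(ascvd_cardiac = "i had a myocardial infarction before.",
                    ascvd_cerebral = "i had a cerebral infarction before.",
                    pancreatitis = "i was hospitalized for pancreatitis before.")
RESP_LIFESTYLE_SENT <- c(reduce_fats = "you should reduce fat intake.",
                         exercise = "do appropriate exercise.",
                         smoking_cessation = "quit smoking.",
                         weight_control = "try to lose weight.",
                         limit_carbohydrate = "limit carbohydrate intake.",
                         limit_alcohol = "limit alcohol.",
                         limit_oil = "cook with less oil.")
PROXY_RELATIONS <- list(male = c("father", "husband", "brother"),
                        female = c("mother", "wife", "sister"))

fmt1 <- function(x) sprintf("%.1f", x)

build_clean_query <- function(a, config) {
  # a: one-row list of sampled attributes; returns the query text
  subj <- if (a$is_proxy) {
    pron <- if (a$gender == "male") "his" else "her"
    sprintf("my %s is %d years old.", a$relation, a$age_years)
  } else if (a$indirect_age) {
    sprintf("i am %s and i am a %s.", a$age_phrase,
            if (a$gender == "male") "man" else "woman")
  } else {
    sprintf("i am a %d year old %s.", a$age_years,
            if (a$gender == "male") "man" else "woman")
  }
  pron_pos <- if (a$is_proxy) {
    if (a$gender == "male") "his" else "her"
  } else "my"
  tg <- if (a$n_tg == 2L) {
    sprintf("%s triglyceride was %s last month and %s mmol/l now.",
            pron_pos, fmt1(a$tg1), fmt1(a$tg2))
  } else if (a$mgdl) {
    sprintf("%s triglyceride came back %d mg/dl.", pron_pos, a$tg_mg)
  } else {
    sprintf("%s triglyceride is %s mmol/l.", pron_pos, fmt1(a$tg2))
  }
  parts <- c(subj,
             if (a$pregnant) {
               if (a$is_proxy) "she is pregnant." else "i am 28 weeks pregnant."
             },
             tg,
             if (a$chol_elevated) sprintf("%s cholesterol is also high.",
                                          pron_pos),
             if (length(a$symptoms)) {
               terms <- vapply(a$symptoms, function(s) a$symptom_terms[[s]],
                               character(1))
               sprintf("there is often %s.", paste(terms, collapse = " and "))
             },
             if (length(a$secondary)) unname(SECONDARY_SENT[a$secondary]),
             if (length(a$lifestyle)) {
               paste0(paste(unname(LIFESTYLE_SENT[a$lifestyle]),
                            collapse = ". "), ".")
             },
             if (length(a$drugs)) {
               sprintf("i am currently taking %s.",
                       paste(unname(DRUG_NAMES[a$drugs]),
                             collapse = " and "))
             },
             if (length(a$factors)) unname(FACTOR_SENT[a$factors]),
             demand_sentence(a$demand, a$demand_phrase))
  paste(parts, collapse = " ")
}

sample_one <- function(x, size = 1L, prob = NULL) {
  # sample() treats a length-1 numeric x as 1:x; always sample from the set
  x[sample.int(length(x), size, prob = prob)]
}

#' Generate a synthetic consultation corpus with ground truth
#'
#' Produces exactly `n_posts` clean posts plus contaminants (duplicate IDs,
#' advertisements, popular-science posts, low-TG non-topic posts) at the
#' configured per-clean-post rates. Clean query texts are slot-filled
#' sentence templates that embed lexicon terms, so every clean post is
#' exactly recoverable by the extraction stage (the generator/extractor
#' oracle contract). Contaminant posts carry no patient labels. Identical
#' `(config, seed)` produces a byte-identical corpus.
#'
#' @param config a [generator_config()].
#' @return list of class `tg_synth` with `posts` (list of `tg_post` in
#'   corpus order), `truth` (data.frame, one row per generated post in the
#'   same order; list-columns for set-valued attributes) and
#'   `response_truth` (data.frame, one row per generated response).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "tg_generator_config"))
  withr::with_seed(as.integer(config$seed), generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  n <- as.integer(config$n_posts)
  cfg <- config
  grids <- list(edge = tg_grid(1.7, 2.2), mild_moderate = tg_grid(2.3, 5.5),
                severe = tg_grid(5.6, 19.9))
  demand_tab <- demand_taxonomy()

  ## ---- clean post attributes (vectorized draws) ----
  platform_type <- ifelse(stats::runif(n) < cfg$platform_mix,
                          "qa_search", "online_consultation")
  platform <- ifelse(platform_type == "qa_search",
                     sample(QA_PLATFORMS, n, replace = TRUE),
                     sample(CONSULT_PLATFORMS, n, replace = TRUE))
  year <- sample(2004:2020, n, replace = TRUE, prob = YEAR_WEIGHTS)
  gender <- ifelse(stats::runif(n) < cfg$gender_mix, "female", "male")
  proxy_p <- ifelse(gender == "female", cfg$proxy_rate_female,
                    cfg$proxy_rate_male)
  is_proxy <- stats::runif(n) < proxy_p
  pregnant <- gender == "female" & stats::runif(n) < cfg$pregnancy_rate
  age_band <- sample(names(cfg$age_mix), n, replace = TRUE,
                     prob = cfg$age_mix)
  age_band[pregnant] <- "mid21_60"  # pregnancies drawn from 21-40
  severity <- sample(names(cfg$severity_mix), n, replace = TRUE,
                     prob = cfg$severity_mix)
  chol <- stats::runif(n) < cfg$chol_co_elevation_rate
  demand <- sample(names(cfg$demand_mix), n, replace = TRUE,
                   prob = cfg$demand_mix)
  n_tg <- ifelse(stats::runif(n) < cfg$multi_tg_rate, 2L, 1L)
  mgdl <- n_tg == 1L & stats::runif(n) < cfg$mgdl_rate
  indirect_age <- !is_proxy & !pregnant &
    stats::runif(n) < cfg$indirect_age_rate

  posts <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    a <- list(gender = gender[i], is_proxy = is_proxy[i],
              pregnant = pregnant[i], chol_elevated = chol[i],
              demand = demand[i], n_tg = n_tg[i], mgdl = mgdl[i],
              indirect_age = FALSE)
    a$relation <- if (a$is_proxy) {
      sample_one(PROXY_RELATIONS[[a$gender]])
    } else NA_character_
    if (a$pregnant && a$is_proxy) a$relation <- "wife"
    a$age_years <- if (a$pregnant) {
      sample_one(21:40)
    } else {
      switch(age_band[i],
             le20 = sample_one(12:20),
             mid21_60 = sample_one(21:60),
             gt60 = sample_one(61:85))
    }
    if (indirect_age[i]) {
      dec <- sample_one(c("twenties", "thirties", "forties", "fifties"))
      a$indirect_age <- TRUE
      a$age_phrase <- paste0("in my ", dec)
      a$age_years <- c(twenties = 25, thirties = 35, forties = 45,
                       fifties = 55)[[dec]]
    }
    v <- sample_one(grids[[severity[i]]])
    if (a$mgdl) {
      a$tg_mg <- as.integer(round(v * MG_DL_PER_MMOL_L))
      a$tg_values <- a$tg_mg / MG_DL_PER_MMOL_L
    } else if (a$n_tg == 2L) {
      a$tg1 <- as.numeric(fmt1(sample_one(round(seq(1.0, v, by = 0.1), 1))))
      a$tg2 <- as.numeric(fmt1(v))
      a$tg_values <- c(a$tg1, a$tg2)
    } else {
      a$tg2 <- as.numeric(fmt1(v))
      a$tg_values <- a$tg2
    }
    a$symptoms <- if (stats::runif(1) < cfg$symptom_rate) {
      sample_one(c("head", "chest", "other"), size = sample_one(1:2),
                 prob = NULL)
    } else character(0)
    a$symptom_terms <- lapply(SYMPTOM_TERM, sample_one)
    a$secondary <- names(cfg$secondary_rates)[
      stats::runif(length(cfg$secondary_rates)) < cfg$secondary_rates]
    a$lifestyle <- if (stats::runif(1) < cfg$lifestyle_mention_rate) {
      sort(sample_one(names(LIFESTYLE_SENT), size = sample_one(1:2)))
    } else character(0)
    a$drugs <- if (stats::runif(1) < cfg$drug_mention_rate) {
      k <- if (stats::runif(1) < cfg$combo_rate) {
        if (stats::runif(1) < cfg$combo3_share) 3L else 2L
      } else 1L
      sort(sample(names(DRUG_NAMES), k,
                  prob = c(0.42, 0.36, 0.15, 0.02, 0.02, 0.03)))
    } else character(0)
    a$factors <- if (length(a$drugs) && stats::runif(1) < cfg$factor_rate) {
      sample_one(names(FACTOR_SENT), size = 1L,
                 prob = c(0.45, 0.38, 0.01, 0.01, 0.15))
    } else character(0)
    row <- demand_tab[demand_tab$label == a$demand, ]
    a$demand_phrase <- sample_one(row$phrases[[1]])
    a$demand_group <- row$group

    posts[[i]] <- raw_post(post_id = sprintf("post%06d", i),
                           platform_name = platform[i],
                           platform_type = platform_type[i],
                           year = year[i],
                           query_text = build_clean_query(a, cfg))
    truth_rows[[i]] <- list(
      post_id = sprintf("post%06d", i), is_contaminant = FALSE,
      contaminant_kind = "none", gender = a$gender, is_proxy = a$is_proxy,
      relation = a$relation, age_years = as.numeric(a$age_years),
      pregnant = a$pregnant, tg_values = list(a$tg_values),
      severity = severity[i], chol_elevated = a$chol_elevated,
      htg_type = if (a$chol_elevated) "tg_plus_chol" else "tg_only",
      demand = a$demand, demand_group = a$demand_group,
      symptoms = list(sort(a$symptoms)), secondary = list(sort(a$secondary)),
      lifestyle = list(a$lifestyle), drugs = list(a$drugs),
      combination_size = if (length(a$drugs) >= 2L) length(a$drugs) else
        NA_integer_,
      factors = list(a$factors),
      platform_type = platform_type[i], year = year[i])
  }

  ## ---- responses for clean posts ----
  resp_rows <- list()
  for (i in seq_len(n)) {
    lam <- cfg$response_count_mean[[platform_type[i]]]
    k <- stats::rpois(1, lam)
    if (k == 0L) next
    sev <- severity[i]
    responses <- vector("list", k)
    for (j in seq_len(k)) {
      ls_flags <- stats::runif(length(cfg$response_lifestyle_rates)) <
        cfg$response_lifestyle_rates
      ls <- names(cfg$response_lifestyle_rates)[ls_flags]
      diet_phrase <- stats::runif(1) < cfg$diet_phrase_rate
      med <- stats::runif(1) < cfg$medication_rate_by_severity[[sev]]
      drugs <- character(0)
      if (med) {
        drugs <- names(cfg$response_drug_rates)[
          stats::runif(length(cfg$response_drug_rates)) <
            cfg$response_drug_rates]
        if (!length(drugs)) drugs <- "statin"  # medication implies >=1 class
      }
      supp <- stats::runif(1) < cfg$supplement_rate[[platform_type[i]]]
      lld <- stats::runif(1) < cfg$lld_rate[[platform_type[i]]]
      sent <- c(unname(RESP_LIFESTYLE_SENT[ls]),
                if (diet_phrase) "also control your diet.",
                if (length(drugs)) sprintf("i recommend %s.",
                                           paste(unname(DRUG_NAMES[drugs]),
                                                 collapse = " and ")),
                if (supp) "you can take some health products as a supplement.",
                if (lld) "follow a lipid-lowering diet.")
      if (!length(sent)) sent <- "please recheck your blood lipid at the hospital."
      if (platform_type[i] == "online_consultation") {
        title <- sample_one(names(TITLE_PROBS), prob = TITLE_PROBS)
        region <- sample_one(REGIONS, prob = REGION_WEIGHTS)
        hosp <- sample_one(c("tertiary", "secondary", "primary"),
                           prob = c(0.5, 0.3, 0.2))
      } else {
        title <- "unknown"; region <- NULL; hosp <- NULL
      }
      rid <- sprintf("%s_r%d", posts[[i]]$post_id, j)
      responses[[j]] <- raw_response(rid, paste(sent, collapse = " "),
                                     responder_title = title,
                                     responder_region = region,
                                     hospital_level = hosp)
      diet_specific <- c("reduce_fats", "limit_carbohydrate", "limit_alcohol",
                         "limit_oil")
      truth_ls <- c(ls, if (diet_phrase && !any(ls %in% diet_specific))
        "diet_control_unspecified")
      resp_rows[[length(resp_rows) + 1L]] <- list(
        post_id = posts[[i]]$post_id, response_id = rid,
        lifestyle = list(truth_ls), drugs = list(sort(drugs)),
        supplements = supp, lipid_lowering_diet = lld,
        medication_suggested = length(drugs) > 0L,
        responder_title = title,
        responder_region = if (is.null(region)) NA_character_ else region,
        hospital_level = if (is.null(hosp)) NA_character_ else hosp)
    }
    posts[[i]]$responses <- responses
  }

  ## ---- contaminants ----
  contam_posts <- list()
  contam_truth <- list()
  contam_key <- numeric(0)
  rates <- cfg$contamination
  add_contam <- function(post, kind, key) {
    contam_posts[[length(contam_posts) + 1L]] <<- post
    contam_truth[[length(contam_truth) + 1L]] <<- list(
      post_id = post$post_id, is_contaminant = TRUE, contaminant_kind = kind,
      gender = NA_character_, is_proxy = NA, relation = NA_character_,
      age_years = NA_real_, pregnant = NA, tg_values = list(numeric(0)),
      severity = NA_character_, chol_elevated = NA, htg_type = NA_character_,
      demand = NA_character_, demand_group = NA_character_,
      symptoms = list(character(0)), secondary = list(character(0)),
      lifestyle = list(character(0)), drugs = list(character(0)),
      combination_size = NA_integer_, factors = list(character(0)),
      platform_type = post$platform_type, year = post$year)
    contam_key[length(contam_key) + 1L] <<- key
  }
  rand_platform <- function() {
    pt <- if (stats::runif(1) < cfg$platform_mix) "qa_search" else
      "online_consultation"
    list(type = pt, name = if (pt == "qa_search") sample_one(QA_PLATFORMS)
         else sample_one(CONSULT_PLATFORMS))
  }
  n_dup <- stats::rbinom(1, n, rates$duplicate_rate)
  if (n_dup > 0) {
    src <- sample.int(n, n_dup, replace = TRUE)
    for (s in src) {
      dup <- posts[[s]]
      dup$responses <- list()
      # key places the duplicate strictly after its source
      add_contam(dup, "duplicate", s + stats::runif(1) * (n + 1 - s))
    }
  }
  n_ad <- stats::rbinom(1, n, rates$ad_rate)
  for (k in seq_len(n_ad)) {
    pl <- rand_platform()
    # advertised product is a fibrate (category IV-a) so the ad is retrieved
    # by the keyword strategy and removed by the filter stage, not earlier
    txt <- sprintf(paste0("special offer: buy %s at a discount, click the ",
                          "link www.lipidmall%d.com for blood lipid health."),
                   sample_one(c("fenofibrate", "bezafibrate", "lipanthyl")), k)
    add_contam(raw_post(sprintf("ad%06d", k), pl$name, pl$type,
                        sample(2004:2020, 1, prob = YEAR_WEIGHTS), txt),
               "advertisement", stats::runif(1) * (n + 1))
  }
  n_sci <- stats::rbinom(1, n, rates$science_rate)
  for (k in seq_len(n_sci)) {
    pl <- rand_platform()
    txt <- paste("triglycerides are a type of blood fat found in human",
                 "plasma. popular science: a balanced diet and regular",
                 "exercise help everyone keep blood lipid in a normal range.")
    add_contam(raw_post(sprintf("sci%06d", k), pl$name, pl$type,
                        sample(2004:2020, 1, prob = YEAR_WEIGHTS), txt),
               "popular_science", stats::runif(1) * (n + 1))
  }
  n_low <- stats::rbinom(1, n, rates$low_tg_rate)
  for (k in seq_len(n_low)) {
    pl <- rand_platform()
    v <- fmt1(sample_one(tg_grid(0.5, 1.6)))
    g <- if (stats::runif(1) < cfg$gender_mix) "woman" else "man"
    txt <- sprintf(paste0("i am a %d year old %s. my triglyceride is %s ",
                          "mmol/l. is this fine?"),
                   sample_one(21:60), g, v)
    add_contam(raw_post(sprintf("low%06d", k), pl$name, pl$type,
                        sample(2004:2020, 1, prob = YEAR_WEIGHTS), txt),
               "non_topic", stats::runif(1) * (n + 1))
  }

  ## ---- interleave: order by sort key (clean post i has key i) ----
  keys <- c(seq_len(n), contam_key)
  ord <- order(keys)
  all_posts <- c(posts, contam_posts)[ord]
  all_truth <- c(truth_rows, contam_truth)[ord]
  truth <- rows_to_df(all_truth,
                      list_cols = c("tg_values", "symptoms", "secondary",
                                    "lifestyle", "drugs", "factors"))
  resp_truth <- if (length(resp_rows)) {
    rows_to_df(resp_rows, list_cols = c("lifestyle", "drugs"))
  } else NULL
  structure(list(posts = all_posts, truth = truth,
                 response_truth = resp_truth, config = cfg),
            class = "tg_synth")
}

#' Write ground truth as a JSONL sidecar
#'
#' @param synth a `tg_synth` from [generate_corpus()].
#' @param path output path.
#' @return number of records written, invisibly.
#' @export
write_truth <- function(synth, path) {
  tr <- synth$truth
  lines <- vapply(seq_len(nrow(tr)), function(i) {
    as.character(jsonlite::toJSON(as.list(tr[i, , drop = FALSE]),
                                  auto_unbox = TRUE, null = "null",
                                  na = "null", digits = NA))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(length(lines))
}
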