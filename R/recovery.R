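set_equal <- function(a, b) {
  identical(sort(as.character(a)), sort(as.character(b)))
}
num_equal <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && all(abs(a - b) <= tol)
}

#' Recovery report: pipeline output vs generator ground truth
#'
#' Joins the pipeline's patient records and filter decisions back to the
#' generator's ground truth and reports (a) per-attribute exact-agreement
#' accuracy over clean posts, (b) contaminant-detection precision and recall
#' per contaminant class, and (c) the absolute error of each recovered class
#' proportion for gender, severity and demand.
#'
#' @param synth a `tg_synth` from [generate_corpus()] (carries the truth).
#' @param records data.frame from [extract_records()] run on the kept posts.
#' @param decisions decisions data.frame from [apply_filters()] run on the
#'   full generated corpus (one row per generated post, corpus order).
#' @return list of class `tg_recovery` with `attribute_accuracy`,
#'   `contaminant_detection`, `proportion_error`.
#' @export
recovery_report <- function(synth, records, decisions = NULL) {
  truth <- synth$truth
  clean <- truth[!truth$is_contaminant, , drop = FALSE]
  extra <- setdiff(records$post_id, truth$post_id)
  if (length(extra)) {
    stop("records contain post_ids absent from ground truth: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  idx <- match(clean$post_id, records$post_id)

  acc_row <- function(attribute, per_post_equal) {
    list(attribute = attribute,
         accuracy = mean(per_post_equal),
         n = length(per_post_equal))
  }
  eq <- function(fun) {
    vapply(seq_len(nrow(clean)), function(i) {
      j <- idx[i]
      if (is.na(j)) return(FALSE)  # clean post lost by the pipeline
      fun(i, j)
    }, logical(1))
  }
  same_scalar <- function(col) {
    eq(function(i, j) identical(clean[[col]][i], records[[col]][j]))
  }
  rows <- list(
    acc_row("gender", same_scalar("gender")),
    acc_row("proxy", same_scalar("is_proxy")),
    acc_row("pregnancy", same_scalar("pregnant")),
    acc_row("age", eq(function(i, j) {
      (is.na(clean$age_years[i]) && is.na(records$age_years[j])) ||
        isTRUE(clean$age_years[i] == records$age_years[j])
    })),
    acc_row("tg_values", eq(function(i, j) {
      num_equal(clean$tg_values[[i]], records$tg_values[[j]])
    })),
    acc_row("severity", same_scalar("severity")),
    acc_row("chol_elevated", same_scalar("chol_elevated")),
    acc_row("demand", same_scalar("demand")),
    acc_row("symptoms", eq(function(i, j) {
      set_equal(clean$symptoms[[i]], records$symptoms[[j]])
    })),
    acc_row("drugs", eq(function(i, j) {
      set_equal(clean$drugs[[i]], records$drugs[[j]])
    })),
    acc_row("lifestyle", eq(function(i, j) {
      set_equal(clean$lifestyle[[i]], records$lifestyle[[j]])
    })),
    acc_row("factors", eq(function(i, j) {
      set_equal(clean$factors[[i]], records$factors[[j]])
    }))
  )
  attribute_accuracy <- rows_to_df(rows)

  contaminant_detection <- NULL
  if (!is.null(decisions)) {
    if (nrow(decisions) != nrow(truth)) {
      stop("decisions (", nrow(decisions), " rows) do not align with the ",
           "generated corpus (", nrow(truth), " posts)", call. = FALSE)
    }
    kinds <- c("duplicate", "advertisement", "popular_science", "non_topic")
    crow <- lapply(kinds, function(k) {
      pred <- decisions$rule_fired == k
      actual <- truth$contaminant_kind == k
      tp <- sum(pred & actual); fp <- sum(pred & !actual)
      fn <- sum(!pred & actual)
      list(kind = k, tp = as.integer(tp), fp = as.integer(fp),
           fn = as.integer(fn),
           precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
    })
    contaminant_detection <- rows_to_df(crow)
  }

  prop_rows <- list()
  prop_err <- function(attribute, truth_vals, rec_vals) {
    for (cl in sort(unique(stats::na.omit(truth_vals)))) {
      tp <- mean(truth_vals == cl, na.rm = TRUE)
      rp <- if (all(is.na(rec_vals))) NA_real_ else
        mean(rec_vals == cl, na.rm = TRUE)
      prop_rows[[length(prop_rows) + 1L]] <<- list(
        attribute = attribute, class = cl, truth_prop = tp,
        recovered_prop = rp, abs_error = abs(tp - rp))
    }
  }
  rec_clean <- records[stats::na.omit(idx), , drop = FALSE]
  prop_err("gender", clean$gender, rec_clean$gender)
  prop_err("severity", clean$severity, rec_clean$severity)
  prop_err("demand", clean$demand, rec_clean$demand)

  structure(list(attribute_accuracy = attribute_accuracy,
                 contaminant_detection = contaminant_detection,
                 proportion_error = rows_to_df(prop_rows)),
            class = "tg_recovery")
}
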