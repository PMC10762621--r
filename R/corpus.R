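#' @importFrom jsonlite fromJSON toJSON
NULL

PLATFORM_TYPES <- c("qa_search", "online_consultation")
RESPONDER_TITLES <- c("chief", "associate_chief", "attending", "resident",
                      "nurse", "other", "unknown")
YEAR_RANGE <- c(2004L, 2020L)

#' Construct a single consultation response
#'
#' @param response_id unique id within the post.
#' @param text response body (may be empty).
#' @param responder_title one of `"chief"`, `"associate_chief"`,
#'   `"attending"`, `"resident"`, `"nurse"`, `"other"`, `"unknown"`, or `NULL`.
#' @param responder_region free-text region (e.g. a province), or `NULL`.
#' @param hospital_level free-text hospital tier, or `NULL`.
#' @return a list with class `tg_response`.
#' @export
raw_response <- function(response_id, text = "", responder_title = NULL,
                         responder_region = NULL, hospital_level = NULL) {
  stopifnot(is.character(response_id), length(response_id) == 1L,
            nzchar(response_id))
  if (!is.null(responder_title) && !responder_title %in% RESPONDER_TITLES) {
    stop("unknown responder_title: ", responder_title, call. = FALSE)
  }
  structure(list(response_id = response_id, text = as.character(text)[1],
                 responder_title = responder_title,
                 responder_region = responder_region,
                 hospital_level = hospital_level),
            class = "tg_response")
}

#' Construct a single consultation post
#'
#' A post is one query on an online platform plus its ordered replies.
#' Platform type distinguishes peer Q&A search platforms from online
#' consultation platforms where clinicians answer.
#'
#' @param post_id nonempty string, unique within a corpus (duplicates are a
#'   contamination class handled by [apply_filters()]).
#' @param platform_name short platform name.
#' @param platform_type `"qa_search"` or `"online_consultation"`.
#' @param year integer in 2004--2020 (the surveillance window).
#' @param query_text the patient's query.
#' @param responses list of [raw_response()] objects.
#' @return a list with class `tg_post`.
#' @export
raw_post <- function(post_id, platform_name, platform_type, year,
                     query_text, responses = list()) {
  post <- structure(list(post_id = post_id,
                         platform = platform_name,
                         platform_type = platform_type,
                         year = as.integer(year),
                         query_text = query_text,
                         responses = responses),
                    class = "tg_post")
  validate_post(post)
  post
}

validate_post <- function(post, line = NULL) {
  where <- if (is.null(line)) "" else sprintf(" (line %d)", line)
  fail <- function(...) stop(sprintf(...), where, call. = FALSE)
  if (!is.character(post$post_id) || length(post$post_id) != 1L ||
      is.na(post$post_id) || !nzchar(post$post_id)) {
    fail("post_id must be a nonempty string")
  }
  if (!is.character(post$platform) || !nzchar(post$platform %||% "")) {
    fail("post %s: platform name must be nonempty", post$post_id)
  }
  if (!isTRUE(post$platform_type %in% PLATFORM_TYPES)) {
    fail("post %s: unknown platform_type '%s'", post$post_id,
         as.character(post$platform_type %||% "<missing>"))
  }
  yr <- post$year
  if (!is.numeric(yr) || length(yr) != 1L || is.na(yr) ||
      yr < YEAR_RANGE[1] || yr > YEAR_RANGE[2]) {
    fail("post %s: year %s outside %d-%d", post$post_id,
         as.character(yr %||% "<missing>"), YEAR_RANGE[1], YEAR_RANGE[2])
  }
  if (!is.character(post$query_text) || length(post$query_text) != 1L) {
    fail("post %s: query_text must be a string", post$post_id)
  }
  ids <- vapply(post$responses, function(r) r$response_id %||% "", character(1))
  if (anyDuplicated(ids)) {
    fail("post %s: duplicate response_id within post", post$post_id)
  }
  invisible(post)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

post_to_json <- function(post) {
  resp <- lapply(post$responses, function(r) {
    list(response_id = r$response_id,
         text = r$text,
         responder_title = r$responder_title,
         responder_region = r$responder_region,
         hospital_level = r$hospital_level)
  })
  obj <- list(post_id = post$post_id,
              platform = post$platform,
              platform_type = post$platform_type,
              year = post$year,
              query_text = post$query_text,
              responses = resp)
  as.character(toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA))
}

post_from_json <- function(line, lineno) {
  obj <- tryCatch(fromJSON(line, simplifyVector = FALSE),
                  error = function(e) {
                    stop(sprintf("malformed JSON at line %d: %s", lineno,
                                 conditionMessage(e)), call. = FALSE)
                  })
  responses <- lapply(obj$responses %||% list(), function(r) {
    structure(list(response_id = r$response_id,
                   text = r$text %||% "",
                   responder_title = r$responder_title,
                   responder_region = r$responder_region,
                   hospital_level = r$hospital_level),
              class = "tg_response")
  })
  post <- structure(list(post_id = obj$post_id,
                         platform = obj$platform,
                         platform_type = obj$platform_type,
                         year = if (is.null(obj$year)) NA_integer_ else
                           as.integer(obj$year),
                         query_text = obj$query_text,
                         responses = responses),
                    class = "tg_post")
  validate_post(post, line = lineno)
  post
}

#' Read a consultation corpus from JSONL
#'
#' One JSON object per line, schema:
#' `{"post_id", "platform", "platform_type", "year", "query_text",
#' "responses": [{"response_id", "text", "responder_title",
#' "responder_region", "hospital_level"}]}`.
#' Every record is validated (year window, platform type, nonempty ids);
#' errors name the offending line.
#'
#' @param path path to a JSONL file (UTF-8).
#' @return list of `tg_post` objects in file order.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("no such corpus file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) out[[i]] <- post_from_json(lines[i], i)
  out
}

#' Write a consultation corpus as JSONL
#'
#' Serialization is canonical (fixed key order, fixed number formatting), so
#' write/read/write round trips are byte-identical.
#'
#' @param posts list of `tg_post` objects.
#' @param path output path.
#' @return number of records written, invisibly.
#' @export
write_corpus <- function(posts, path) {
  for (p in posts) validate_post(p)
  lines <- vapply(posts, post_to_json, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = TRUE)
  invisible(length(lines))
}
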