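#' Construct an interaction set
#'
#' The central container: one row per interaction (a blog post or a comment
#' on a post), together with the closed calendar interval the set covers.
#' Posts are their own thread root (`thread_id == item_id`); comments point
#' at the root post of their thread. Comments whose `thread_id` matches no
#' post in the set are retained but recorded as orphans.
#'
#' @param items A data frame with columns `item_id`, `user_id`, `timestamp`
#'   (POSIXct, naive local clock), `kind` (`"post"` or `"comment"`),
#'   `thread_id`, and optionally `text`, `word_count`, `text_hash`.
#'   `word_count` and `text_hash` are (re)computed from `text` when `text`
#'   is present.
#' @param period_start,period_end Dates bounding the analysis period
#'   (closed interval). Default to the date range of `items`.
#' @return An object of class `interaction_set`: a list with elements
#'   `items` (tibble), `period_start`, `period_end`, and `orphans`
#'   (character vector of orphan comment ids).
#' @examples
#' it <- tibble::tibble(
#'   item_id = c("p1", "c1"), user_id = c("u1", "u2"),
#'   timestamp = as.POSIXct(c("2011-01-02 10:00:00", "2011-01-02 11:00:00"),
#'                          tz = "UTC"),
#'   kind = c("post", "comment"), thread_id = c("p1", "p1"),
#'   text = c("first post", "well done")
#' )
#' interaction_set(it)
#' @export
interaction_set <- function(items, period_start = NULL, period_end = NULL) {
  items <- tibble::as_tibble(items)
  required <- c("item_id", "user_id", "timestamp", "kind", "thread_id")
  missing <- setdiff(required, names(items))
  if (length(missing) > 0) {
    stop("missing required field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  items$item_id <- as.character(items$item_id)
  items$user_id <- as.character(items$user_id)
  items$thread_id <- as.character(items$thread_id)
  items$kind <- as.character(items$kind)
  if (!inherits(items$timestamp, "POSIXct")) {
    stop("timestamp must be POSIXct; use read_interactions() for text input",
         call. = FALSE)
  }
  if (anyNA(items$timestamp)) {
    stop("unparseable timestamp at row(s): ",
         paste(head(which(is.na(items$timestamp)), 5), collapse = ", "),
         call. = FALSE)
  }
  bad_kind <- setdiff(unique(items$kind), c("post", "comment"))
  if (length(bad_kind) > 0) {
    stop("kind must be 'post' or 'comment'; found: ",
         paste(bad_kind, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(items$item_id) > 0) {
    stop("item_id values must be unique", call. = FALSE)
  }
  bad_root <- items$kind == "post" & items$thread_id != items$item_id
  if (any(bad_root)) {
    stop("posts must satisfy thread_id == item_id (violated at row ",
         which(bad_root)[1], ")", call. = FALSE)
  }

  if (!"text" %in% names(items)) items$text <- NA_character_
  has_text <- !is.na(items$text)
  wc <- if ("word_count" %in% names(items)) as.integer(items$word_count)
        else rep(NA_integer_, nrow(items))
  wc[has_text] <- count_words(items$text[has_text])
  items$word_count <- wc
  th <- if ("text_hash" %in% names(items)) as.character(items$text_hash)
        else rep(NA_character_, nrow(items))
  th[has_text] <- text_sha1(items$text[has_text])
  items$text_hash <- th

  dts <- as.Date(items$timestamp, tz = attr_tz(items$timestamp))
  if (is.null(period_start)) {
    period_start <- if (nrow(items) > 0) min(dts) else Sys.Date()
  }
  if (is.null(period_end)) {
    period_end <- if (nrow(items) > 0) max(dts) else Sys.Date()
  }
  period_start <- as.Date(period_start)
  period_end <- as.Date(period_end)
  if (period_end < period_start) stop("period_end precedes period_start",
                                      call. = FALSE)
  if (nrow(items) > 0 && (any(dts < period_start) || any(dts > period_end))) {
    stop("timestamps fall outside [period_start, period_end]", call. = FALSE)
  }

  post_ids <- items$item_id[items$kind == "post"]
  is_orphan <- items$kind == "comment" & !(items$thread_id %in% post_ids)
  structure(
    list(items = items, period_start = period_start,
         period_end = period_end, orphans = items$item_id[is_orphan]),
    class = "interaction_set"
  )
}

attr_tz <- function(x) {
  tz <- attr(x, "tzone")
  if (is.null(tz) || identical(tz, "")) "UTC" else tz
}

#' @export
print.interaction_set <- function(x, ...) {
  cat(sprintf(
    "<interaction_set> %d items (%d posts, %d comments), %d users\n",
    nrow(x$items), sum(x$items$kind == "post"),
    sum(x$items$kind == "comment"),
    length(unique(x$items$user_id))
  ))
  cat(sprintf("  period: %s to %s\n", x$period_start, x$period_end))
  if (length(x$orphans) > 0) {
    cat(sprintf("  orphan comments: %d\n", length(x$orphans)))
  }
  invisible(x)
}

#' Number of items in an interaction set
#' @param s An `interaction_set`.
#' @return Integer count of items.
#' @export
n_items <- function(s) {
  stopifnot(inherits(s, "interaction_set"))
  nrow(s$items)
}

#' Items of an interaction set as a tibble
#' @param s An `interaction_set`.
#' @return The `items` tibble.
#' @export
interactions <- function(s) {
  stopifnot(inherits(s, "interaction_set"))
  s$items
}

#' Whitespace-token word count
#'
#' Number of whitespace-delimited tokens; the word-length measure used for
#' item content throughout the package.
#'
#' @param text Character vector.
#' @return Integer vector of token counts (0 for empty or all-whitespace).
#' @export
count_words <- function(text) {
  out <- integer(length(text))
  nonempty <- !is.na(text) & trimws(text) != ""
  out[nonempty] <- lengths(strsplit(trimws(text[nonempty]), "\\s+"))
  out[is.na(text)] <- NA_integer_
  out
}

#' SHA-1 fingerprint of item text
#'
#' 160-bit digest of the exact text bytes with no normalisation; two items
#' share a fingerprint if and only if their texts are byte-identical (up to
#' digest collision, which is negligible at these scales).
#'
#' @param text Character vector.
#' @return Character vector of 40-hex-digit digests.
#' @export
text_sha1 <- function(text) {
  vapply(text, function(t) digest::digest(t, algo = "sha1", serialize = FALSE),
         character(1), USE.NAMES = FALSE)
}
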