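# Small in-code fixtures shared across test files.

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# A minimal hand-built set: `spec` rows of (id, user, time, kind, thread,
# text). Returns an interaction_set.
make_set <- function(..., period_start = NULL, period_end = NULL) {
  rows <- list(...)
  df <- tibble::tibble(
    item_id = vapply(rows, `[[`, "", 1),
    user_id = vapply(rows, `[[`, "", 2),
    timestamp = ts_utc(vapply(rows, `[[`, "", 3)),
    kind = vapply(rows, `[[`, "", 4),
    thread_id = vapply(rows, `[[`, "", 5),
    text = vapply(rows, `[[`, "", 6)
  )
  interaction_set(df, period_start, period_end)
}

# Random thread-structured stream for property tests: n_threads posts,
# each with a Poisson number of comments; texts drawn from a tiny
# vocabulary so exact repeats occur naturally.
random_stream <- function(n_threads = 8, mean_comments = 3, n_users = 6,
                          vocab = c("aa bb", "cc", "dd ee ff", "gg hh"),
                          start = as.Date("2012-03-01")) {
  rows <- list()
  serial <- 0
  for (t in seq_len(n_threads)) {
    serial <- serial + 1
    pid <- sprintf("p%03d", t)
    ptime <- start + (t - 1) %% 20
    rows[[length(rows) + 1]] <- tibble::tibble(
      item_id = pid, user_id = sprintf("u%d", sample.int(n_users, 1)),
      timestamp = ts_utc(paste(ptime, "09:00:00")) + serial,
      kind = "post", thread_id = pid, text = sample(vocab, 1))
    for (c in seq_len(rpois(1, mean_comments))) {
      serial <- serial + 1
      rows[[length(rows) + 1]] <- tibble::tibble(
        item_id = sprintf("c%03d_%02d", t, c),
        user_id = sprintf("u%d", sample.int(n_users, 1)),
        timestamp = ts_utc(paste(ptime, "10:00:00")) + serial * 61,
        kind = "comment", thread_id = pid, text = sample(vocab, 1))
    }
  }
  interaction_set(dplyr::bind_rows(rows))
}

# Independent O(n^2) dedup oracle: within each thread, pairwise exact
# text comparison; keeps the earliest (then lexicographically smallest
# id) of every equal-text clique.
dedup_oracle_ids <- function(s) {
  items <- s$items
  keep <- character()
  for (th in unique(items$thread_id)) {
    sub <- items[items$thread_id == th, , drop = FALSE]
    taken <- rep(FALSE, nrow(sub))
    ord <- order(sub$timestamp, sub$item_id)
    sub <- sub[ord, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      if (taken[i]) next
      keep <- c(keep, sub$item_id[i])
      for (j in seq_len(nrow(sub))) {
        if (j > i && identical(sub$text[j], sub$text[i])) taken[j] <- TRUE
      }
    }
  }
  sort(keep)
}

# Brute-force window maximum: scan every candidate start date.
window_max_oracle <- function(dates, counts, year, window_days = 90) {
  y0 <- as.Date(sprintf("%d-01-01", year))
  y1 <- as.Date(sprintf("%d-12-31", year))
  window_days <- min(window_days, as.integer(y1 - y0) + 1L)
  best <- 0L
  d <- y0
  while (d + window_days - 1 <= y1) {
    inwin <- dates >= d & dates <= d + window_days - 1
    best <- max(best, sum(counts[inwin]))
    d <- d + 1
  }
  as.integer(best)
}

# Random user-year timeline of `n_events` active days.
random_timeline <- function(year = 2012, n_events = 20, max_per_day = 4) {
  y0 <- as.Date(sprintf("%d-01-01", year))
  days <- sort(sample(0:364, n_events))
  tibble::tibble(date = y0 + days,
                 n = sample.int(max_per_day, n_events, replace = TRUE))
}

# All-pairs AUROC oracle with half-credit ties.
auroc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
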