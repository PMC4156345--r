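#' Default engagement mixture for the synthetic generator
#'
#' A finite mixture of behavioural classes rather than a continuous power
#' law: the simplest mechanism that reproduces the heavy-tailed activity
#' distribution seen in real support networks while giving categorical
#' ground truth for classifier-recovery tests. The `high` class emits at a
#' rate that clears the highly-engaged (180 items / 90 days) bar, the
#' `fleeting` class stays at or below two items in total on most draws,
#' and `regular` sits in between.
#'
#' @return A tibble with columns `class`, `prop` (mixing proportion),
#'   `items_per_day` (mean items per active day), `active_days` (mean
#'   number of active days over the user's tenure), `decay_days`
#'   (timescale over which active days concentrate after first activity;
#'   `Inf` for uniform).
#' @export
default_engagement_mixture <- function() {
  tibble::tibble(
    class = c("high", "regular", "fleeting"),
    prop = c(0.03, 0.47, 0.50),
    items_per_day = c(4.0, 1.2, 0.3),
    active_days = c(250, 35, 1),
    decay_days = c(300, 90, 14)
  )
}

#' Simulation configuration for a synthetic OCSN interaction stream
#'
#' Parameterises [simulate_network()] and [inject_artifacts()]. Defaults
#' emulate a two-year extract from a mid-sized cessation support network:
#' a heavy-tailed per-user activity distribution (via the engagement
#' mixture), a January-peaked / December-trough seasonal profile of first
#' activities, a work-week-high day-of-week profile with a Friday dip and
#' low weekends, threaded comments averaging `comment_rate` per post, one
#' staff commenter account, and occasional verbatim re-submissions.
#'
#' @param n_users Number of user accounts to simulate.
#' @param period_start,period_end Closed calendar interval covered.
#' @param engagement_mixture Data frame as in
#'   [default_engagement_mixture()]; `prop` must sum to 1.
#' @param monthly_arrival_weights 12 nonnegative weights for the calendar
#'   month of a user's first activity (January first).
#' @param weekday_weights 7 nonnegative weights modulating daily emission
#'   rates (Monday first); internally normalised to mean 1.
#' @param comment_rate Mean comments attracted per post; also sets the
#'   post/comment split of emissions (an emission is a post with
#'   probability `1/(1 + comment_rate)`).
#' @param staff_reply_prob Probability a post receives one staff comment
#'   when artifacts are injected.
#' @param duplicate_prob Probability an item is accidentally re-submitted
#'   verbatim shortly afterwards when artifacts are injected.
#' @param year_growth Relative weight of each successive calendar year in
#'   the arrival distribution (network growth).
#' @param vocab_size,mean_words Synthetic text generation: vocabulary size
#'   and mean words per item (word counts are 2 + negative binomial).
#' @param staff_user_id Reserved id of the single staff account.
#' @param seed Integer seed; identical configurations give bit-identical
#'   streams.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_users = 2000,
                       period_start = as.Date("2011-01-01"),
                       period_end = as.Date("2012-12-31"),
                       engagement_mixture = default_engagement_mixture(),
                       monthly_arrival_weights = c(1.8, 1.2, 1.1, 1.0, 1.3,
                                                   1.0, 0.9, 0.9, 0.9, 0.9,
                                                   0.8, 0.6),
                       weekday_weights = c(1.0, 1.05, 1.0, 0.95, 0.8,
                                           0.55, 0.6),
                       comment_rate = 6,
                       staff_reply_prob = 0.06,
                       duplicate_prob = 0.004,
                       year_growth = 1.5,
                       vocab_size = 800,
                       mean_words = 16,
                       staff_user_id = "quitline_staff",
                       seed = 1L) {
  engagement_mixture <- tibble::as_tibble(engagement_mixture)
  cfg <- structure(
    list(n_users = as.integer(n_users),
         period_start = as.Date(period_start),
         period_end = as.Date(period_end),
         engagement_mixture = engagement_mixture,
         monthly_arrival_weights = as.numeric(monthly_arrival_weights),
         weekday_weights = as.numeric(weekday_weights),
         comment_rate = comment_rate,
         staff_reply_prob = staff_reply_prob,
         duplicate_prob = duplicate_prob,
         year_growth = year_growth,
         vocab_size = as.integer(vocab_size),
         mean_words = mean_words,
         staff_user_id = staff_user_id,
         seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  mix <- cfg$engagement_mixture
  need <- c("class", "prop", "items_per_day", "active_days", "decay_days")
  if (!all(need %in% names(mix))) {
    stop("engagement_mixture needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(mix$prop) - 1) > 1e-8) {
    stop("engagement_mixture proportions must sum to 1", call. = FALSE)
  }
  if (any(mix$items_per_day < 0) || any(mix$active_days < 0) ||
      cfg$comment_rate < 0 || cfg$mean_words < 0) {
    stop("rates must be nonnegative", call. = FALSE)
  }
  if (cfg$n_users < 0) stop("n_users must be nonnegative", call. = FALSE)
  if (length(cfg$monthly_arrival_weights) != 12 ||
      any(cfg$monthly_arrival_weights < 0)) {
    stop("monthly_arrival_weights must be 12 nonnegative values",
         call. = FALSE)
  }
  if (length(cfg$weekday_weights) != 7 || any(cfg$weekday_weights < 0)) {
    stop("weekday_weights must be 7 nonnegative values", call. = FALSE)
  }
  for (p in c("staff_reply_prob", "duplicate_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(p, " must be in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$period_end < cfg$period_start) {
    stop("period_end precedes period_start", call. = FALSE)
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d users, %s to %s, seed %d\n",
              x$n_users, x$period_start, x$period_end, x$seed))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s (%.0f%%)", x$engagement_mixture$class,
                            100 * x$engagement_mixture$prop),
                    collapse = ", ")))
  invisible(x)
}

with_sim_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

random_texts <- function(n, vocab_size, mean_words, tag = NULL) {
  if (n == 0) return(character())
  wc <- 2L + rnbinom(n, size = 2, mu = max(mean_words - 2, 0.1))
  vocab <- sprintf("w%03d", seq_len(vocab_size))
  words <- sample(vocab, sum(wc), replace = TRUE)
  grp <- rep(seq_len(n), wc)
  texts <- vapply(split(words, grp), paste, character(1), collapse = " ")
  names(texts) <- NULL
  if (!is.null(tag)) {
    # unique serial token guarantees injected texts collide with nothing
    texts <- paste(texts, sprintf("%s%06d", tag, seq_len(n)))
  }
  texts
}

#' Simulate a synthetic OCSN interaction stream
#'
#' Each user draws an engagement class from the mixture, a first-activity
#' date (calendar month by `monthly_arrival_weights` scaled by
#' `year_growth`, day uniform within month), and a set of active days that
#' concentrates after first activity (exponential decay with the class
#' timescale `decay_days`). On each active day the user emits a Poisson
#' number of items at the class rate modulated by `weekday_weights`, with
#' at least one item on the first active day. An emission is a blog post
#' with probability `1/(1 + comment_rate)`, otherwise a comment attached
#' to a post chosen uniformly from the current and previous three days, so
#' that posts attract `comment_rate` comments on average. The stream
#' contains no staff items and no duplicates; use [inject_artifacts()] to
#' add those.
#'
#' @param config A [sim_config()].
#' @return A list with `set` (an [interaction_set]) and `truth` (ground
#'   truth: `$users` with `user_id`, `true_class`, `first_activity_date`;
#'   `$items` with per-item `is_injected_duplicate` and `is_staff` flags,
#'   all `FALSE` here).
#' @examples
#' sim <- simulate_network(sim_config(n_users = 50, seed = 42))
#' sim$set
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, simulate_network_impl(config))
}

simulate_network_impl <- function(config) {
  empty <- function() {
    items <- tibble::tibble(item_id = character(), user_id = character(),
                            timestamp = as.POSIXct(character(), tz = "UTC"),
                            kind = character(), thread_id = character(),
                            text = character())
    list(set = interaction_set(items, config$period_start, config$period_end),
         truth = new_ground_truth(
           users = tibble::tibble(user_id = character(),
                                  true_class = character(),
                                  first_activity_date = as.Date(character())),
           items = tibble::tibble(item_id = character(),
                                  is_injected_duplicate = logical(),
                                  is_staff = logical())))
  }
  if (config$n_users == 0) return(empty())

  days <- seq(config$period_start, config$period_end, by = "day")
  n_days <- length(days)
  mon <- as.integer(format(days, "%m"))
  yr <- as.integer(format(days, "%Y"))
  dow <- as.integer(format(days, "%u")) # 1 = Monday
  wweights <- config$weekday_weights / mean(config$weekday_weights)

  # per-day arrival weights: seasonal month profile x annual growth,
  # spread uniformly over the days of each month
  mdays <- ave(rep(1, n_days), paste(yr, mon), FUN = sum)
  arrival_w <- config$monthly_arrival_weights[mon] *
    config$year_growth^(yr - min(yr)) / mdays
  if (sum(arrival_w) <= 0) stop("arrival weights sum to zero", call. = FALSE)

  mix <- config$engagement_mixture
  cls_idx <- sample.int(nrow(mix), config$n_users, replace = TRUE,
                        prob = mix$prop)
  first_day_idx <- sample.int(n_days, config$n_users, replace = TRUE,
                              prob = arrival_w)

  # active-day offsets per user
  user_rows <- vector("list", config$n_users)
  for (u in seq_len(config$n_users)) {
    k <- cls_idx[u]
    tenure <- n_days - first_day_idx[u] + 1L
    target <- mix$active_days[k]
    n_act <- 1L + rpois(1, max(target - 1, 0))
    n_act <- min(n_act, tenure)
    offs <- 0L
    if (n_act > 1L) {
      pool <- seq_len(tenure - 1L) # offsets 1..tenure-1
      w <- exp(-pool / mix$decay_days[k])
      if (!any(w > 0)) w <- rep(1, length(pool))
      offs <- c(0L, sort(sample(pool, n_act - 1L, prob = w)))
    }
    didx <- first_day_idx[u] + offs
    lambda <- mix$items_per_day[k] * wweights[dow[didx]]
    n_it <- rpois(length(didx), lambda)
    n_it[1] <- 1L + n_it[1] # at least one item on the first active day
    keep <- n_it > 0
    if (!any(keep)) next
    user_rows[[u]] <- tibble::tibble(user = u, day = didx[keep],
                                     n = n_it[keep])
  }
  em <- dplyr::bind_rows(user_rows)
  if (is.null(em) || nrow(em) == 0) return(empty())

  # expand to one row per item, in day order
  em <- em[order(em$day), , drop = FALSE]
  it_day <- rep(em$day, em$n)
  it_user <- rep(em$user, em$n)
  n_total <- length(it_day)
  draft_sec <- runif(n_total, 8 * 3600, 23 * 3600) # active hours of the day
  p_post <- 1 / (1 + config$comment_rate)
  is_post_draw <- runif(n_total) < p_post

  # day-by-day assembly: posts join the attachment pool, comments attach
  # to a post from the current or previous three days
  kind <- character(n_total)
  parent <- character(n_total)
  ts_sec <- numeric(n_total) # seconds since period start
  item_id <- sprintf("i%07d", seq_len(n_total))
  pool_day <- integer(0)
  pool_id <- character(0)
  pool_sec <- numeric(0)
  day_split <- split(seq_len(n_total), it_day)
  for (d_chr in names(day_split)) {
    d <- as.integer(d_chr)
    idx <- day_split[[d_chr]]
    idx <- idx[order(draft_sec[idx])]
    base_sec <- (d - 1) * 86400
    live <- pool_day >= d - 3
    pool_day <- pool_day[live]; pool_id <- pool_id[live]
    pool_sec <- pool_sec[live]
    for (i in idx) {
      make_post <- is_post_draw[i] || length(pool_id) == 0
      if (make_post) {
        kind[i] <- "post"
        parent[i] <- item_id[i]
        ts_sec[i] <- base_sec + draft_sec[i]
        pool_day <- c(pool_day, d)
        pool_id <- c(pool_id, item_id[i])
        pool_sec <- c(pool_sec, ts_sec[i])
      } else {
        j <- sample.int(length(pool_id), 1)
        kind[i] <- "comment"
        parent[i] <- pool_id[j]
        t0 <- base_sec + draft_sec[i]
        # keep the comment strictly after its post
        ts_sec[i] <- if (pool_sec[j] >= t0) {
          pool_sec[j] + runif(1, 60, 3600)
        } else t0
      }
    }
  }
  day_end <- n_days * 86400 - 1
  ts_sec <- pmin(ts_sec, day_end)

  texts <- random_texts(n_total, config$vocab_size, config$mean_words)
  origin <- as.POSIXct(paste(config$period_start, "00:00:00"), tz = "UTC")
  items <- tibble::tibble(
    item_id = item_id,
    user_id = sprintf("u%05d", it_user),
    timestamp = origin + floor(ts_sec),
    kind = kind,
    thread_id = parent,
    text = texts
  )
  items <- items[order(items$timestamp, items$item_id), , drop = FALSE]

  first_dates <- days[first_day_idx]
  truth <- new_ground_truth(
    users = tibble::tibble(user_id = sprintf("u%05d", seq_len(config$n_users)),
                           true_class = mix$class[cls_idx],
                           first_activity_date = first_dates),
    items = tibble::tibble(item_id = items$item_id,
                           is_injected_duplicate = FALSE,
                           is_staff = FALSE))
  list(set = interaction_set(items, config$period_start, config$period_end),
       truth = truth)
}

new_ground_truth <- function(users, items) {
  structure(list(users = users, items = items), class = "ocsn_ground_truth")
}

#' @export
print.ocsn_ground_truth <- function(x, ...) {
  cat(sprintf("<ocsn_ground_truth> %d users, %d items (%d duplicates, %d staff)\n",
              nrow(x$users), nrow(x$items),
              sum(x$items$is_injected_duplicate), sum(x$items$is_staff)))
  invisible(x)
}

#' Inject data-collection artifacts into a clean stream
#'
#' Adds the two artifacts a scraped extract carries: (i) accidental
#' verbatim re-submissions — with probability `duplicate_prob` an item is
#' copied into its own thread 1-60 seconds later; and (ii) staff replies —
#' each post receives one comment from the reserved staff account with
#' probability `staff_reply_prob`. `n_duplicates`/`n_staff` override the
#' probabilities with exact counts (items and posts sampled at random),
#' which is convenient for constructing extracts with a known cleaning
#' arithmetic. Everything injected is flagged in the returned ground
#' truth, so [clean_pipeline()] can be checked to invert the injection
#' exactly.
#'
#' @param s An [interaction_set] with no staff items or duplicates yet.
#' @param config A [sim_config()] (supplies the probabilities, staff id,
#'   text parameters and seed).
#' @param n_duplicates,n_staff Optional exact counts overriding
#'   `duplicate_prob` and `staff_reply_prob`.
#' @return A list with `set` (augmented [interaction_set]) and `truth`
#'   (`$items` flags covering every item of the returned set).
#' @export
inject_artifacts <- function(s, config, n_duplicates = NULL, n_staff = NULL) {
  stopifnot(inherits(s, "interaction_set"), inherits(config, "sim_config"))
  with_sim_seed(config$seed, inject_artifacts_impl(s, config, n_duplicates,
                                                   n_staff))
}

inject_artifacts_impl <- function(s, config, n_duplicates, n_staff) {
  items <- s$items
  n <- nrow(items)
  end_ts <- as.POSIXct(paste(s$period_end, "23:59:59"), tz = "UTC")

  # verbatim re-submissions, same thread, 1-60 s later
  if (is.null(n_duplicates)) {
    dup_src <- which(runif(n) < config$duplicate_prob)
  } else {
    if (n_duplicates > n) stop("n_duplicates exceeds stream size",
                               call. = FALSE)
    dup_src <- sample.int(n, n_duplicates)
  }
  dups <- items[dup_src, , drop = FALSE]
  if (nrow(dups) > 0) {
    dups$item_id <- paste0("zdup_", dups$item_id)
    dups$timestamp <- pmin(dups$timestamp + ceiling(runif(nrow(dups), 1, 60)),
                           end_ts)
    # a re-submitted post lands in the thread it created, as a comment
    dups$kind <- "comment"
    dups$thread_id <- items$thread_id[dup_src]
  }

  # staff replies to posts
  post_rows <- which(items$kind == "post")
  if (is.null(n_staff)) {
    staff_on <- post_rows[runif(length(post_rows)) < config$staff_reply_prob]
  } else {
    if (length(post_rows) == 0 && n_staff > 0) {
      stop("no posts to attach staff comments to", call. = FALSE)
    }
    staff_on <- sample(post_rows, n_staff,
                       replace = n_staff > length(post_rows))
  }
  n_st <- length(staff_on)
  staff <- items[0, , drop = FALSE]
  if (n_st > 0) {
    staff <- tibble::tibble(
      item_id = sprintf("zstaff_%06d", seq_len(n_st)),
      user_id = config$staff_user_id,
      timestamp = pmin(items$timestamp[staff_on] +
                         ceiling(runif(n_st, 3600, 86400)), end_ts),
      kind = "comment",
      thread_id = items$item_id[staff_on],
      text = random_texts(n_st, config$vocab_size, config$mean_words,
                          tag = "staffmsg")
    )
  }

  keep_cols <- c("item_id", "user_id", "timestamp", "kind", "thread_id",
                 "text")
  out_items <- dplyr::bind_rows(items[, keep_cols],
                                dups[, intersect(keep_cols, names(dups))],
                                staff[, intersect(keep_cols, names(staff))])
  out_items <- out_items[order(out_items$timestamp, out_items$item_id), ,
                         drop = FALSE]
  out <- interaction_set(out_items, s$period_start, s$period_end)
  truth <- new_ground_truth(
    users = NULL,
    items = tibble::tibble(
      item_id = out_items$item_id,
      is_injected_duplicate = startsWith(out_items$item_id, "zdup_"),
      is_staff = out_items$user_id == config$staff_user_id))
  list(set = out, truth = truth)
}
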