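#' Annual network and posting metrics
#'
#' The headline per-year report: totals (posts, comments, first-time
#' posts, unique active users), per-user means with normal-approximation
#' 95% margins and interquartile ranges, and the comments-per-post
#' distribution. Per-user denominators are the users active (>= 1 item)
#' in the year; a comment counts toward the year of its own timestamp,
#' while comments-per-post counts all in-thread comments in the set
#' regardless of their year, attributed to the post's year.
#'
#' @param s An [interaction_set].
#' @param year Calendar year.
#' @param timelines A [build_timelines()] result (supplies first-post
#'   dates for the first-time post count).
#' @return An object of class `annual_metrics`: a list with `year`,
#'   `n_posts`, `n_comments`, `n_first_time_posts`, `n_unique_users`,
#'   `mean_posts_per_user`, `margin_posts_per_user`, `iqr_posts_per_user`,
#'   `mean_comments_per_user`, `margin_comments_per_user`,
#'   `iqr_comments_per_user`, `mean_comments_per_post`,
#'   `margin_comments_per_post`, `iqr_comments_per_post`,
#'   `pct_posts_ge3_comments`, `pct_posts_zero_comments`.
#' @export
annual_metrics <- function(s, year, timelines) {
  stopifnot(inherits(s, "interaction_set"),
            inherits(timelines, "user_timelines"))
  items <- s$items
  tz <- attr_tz(items$timestamp)
  items$date <- as.Date(items$timestamp, tz = tz)
  yr_items <- items[format(items$date, "%Y") == as.character(year), ,
                    drop = FALSE]
  users <- unique(yr_items$user_id)
  n_users <- length(users)

  posts_per_user <- as.integer(
    table(factor(yr_items$user_id[yr_items$kind == "post"], levels = users)))
  comments_per_user <- as.integer(
    table(factor(yr_items$user_id[yr_items$kind == "comment"],
                 levels = users)))

  fp <- timelines$users$first_post_date
  n_ftp <- sum(!is.na(fp) & format(fp, "%Y") == as.character(year))

  yr_posts <- yr_items$item_id[yr_items$kind == "post"]
  comments_all <- items[items$kind == "comment", , drop = FALSE]
  cpp <- as.integer(table(factor(comments_all$thread_id,
                                 levels = yr_posts)))

  margin <- function(x) {
    if (length(x) < 2) return(NA_real_)
    qnorm(0.975) * sd(x) / sqrt(length(x))
  }
  iqr2 <- function(x) {
    if (length(x) == 0) return(c(NA_real_, NA_real_))
    unname(quantile(x, c(0.25, 0.75), type = 2))
  }

  structure(list(
    year = as.integer(year),
    n_posts = length(yr_posts),
    n_comments = sum(yr_items$kind == "comment"),
    n_first_time_posts = n_ftp,
    n_unique_users = n_users,
    mean_posts_per_user = if (n_users == 0) NA_real_ else
      mean(posts_per_user),
    margin_posts_per_user = margin(posts_per_user),
    iqr_posts_per_user = iqr2(posts_per_user),
    mean_comments_per_user = if (n_users == 0) NA_real_ else
      mean(comments_per_user),
    margin_comments_per_user = margin(comments_per_user),
    iqr_comments_per_user = iqr2(comments_per_user),
    mean_comments_per_post = if (length(cpp) == 0) NA_real_ else mean(cpp),
    margin_comments_per_post = margin(cpp),
    iqr_comments_per_post = iqr2(cpp),
    pct_posts_ge3_comments = if (length(cpp) == 0) NA_real_ else
      100 * mean(cpp >= 3),
    pct_posts_zero_comments = if (length(cpp) == 0) NA_real_ else
      100 * mean(cpp == 0)),
    class = "annual_metrics")
}

#' @export
print.annual_metrics <- function(x, ...) {
  cat(sprintf("<annual_metrics> %d\n", x$year))
  cat(sprintf("  posts %d, comments %d, first-time posts %d, users %d\n",
              x$n_posts, x$n_comments, x$n_first_time_posts,
              x$n_unique_users))
  cat(sprintf("  posts/user %.1f [±%.1f], comments/user %.1f [±%.1f]\n",
              x$mean_posts_per_user, x$margin_posts_per_user,
              x$mean_comments_per_user, x$margin_comments_per_user))
  cat(sprintf("  comments/post %.1f [±%.1f]; %.0f%% of posts with >=3, %.1f%% with 0\n",
              x$mean_comments_per_post, x$margin_comments_per_post,
              x$pct_posts_ge3_comments, x$pct_posts_zero_comments))
  invisible(x)
}

#' Year-over-year growth of annual metrics
#'
#' Percentage change `100 * (b - a) / a` per scalar metric, rounded to
#' the nearest integer percent for reporting. Metrics with a zero base
#' are flagged `NA`. Argument order is checked (`a` must be the earlier
#' year) rather than silently negated.
#'
#' @param a,b [annual_metrics()] for the earlier and later year.
#' @return A tibble with `metric`, `value_a`, `value_b`, `growth_pct`.
#' @export
metric_growth <- function(a, b) {
  stopifnot(inherits(a, "annual_metrics"), inherits(b, "annual_metrics"))
  if (a$year >= b$year) {
    stop("first argument must be the earlier year (got ", a$year, " vs ",
         b$year, ")", call. = FALSE)
  }
  metrics <- c("n_posts", "n_comments", "n_first_time_posts",
               "n_unique_users", "mean_posts_per_user",
               "mean_comments_per_user", "mean_comments_per_post")
  rows <- lapply(metrics, function(m) {
    va <- a[[m]]
    vb <- b[[m]]
    tibble::tibble(metric = m, value_a = va, value_b = vb,
                   growth_pct = if (is.na(va) || va == 0) NA_real_
                                else round(100 * (vb - va) / va))
  })
  dplyr::bind_rows(rows)
}

#' Most active users of a year
#'
#' Users ranked by total items (posts + comments) in the year,
#' descending, ties broken by user id; with distinct active days and the
#' inclusive activity span (last minus first interaction date in the
#' year, plus one, so a user active on a single day has span 1 and a
#' user active 1 Jan to 31 Dec of a leap year has span 366).
#'
#' @param s An [interaction_set].
#' @param year Calendar year.
#' @param n Number of rows (default 20).
#' @return A tibble with `rank`, `user_id`, `blog_posts`, `comments`,
#'   `distinct_days_active`, `activity_span_days`.
#' @export
top_users <- function(s, year, n = 20) {
  stopifnot(inherits(s, "interaction_set"), n >= 1)
  items <- s$items
  tz <- attr_tz(items$timestamp)
  items$date <- as.Date(items$timestamp, tz = tz)
  yr_items <- items[format(items$date, "%Y") == as.character(year), ,
                    drop = FALSE]
  out <- yr_items |>
    dplyr::group_by(user_id) |>
    dplyr::summarise(
      blog_posts = sum(kind == "post"),
      comments = sum(kind == "comment"),
      distinct_days_active = length(unique(date)),
      activity_span_days = as.integer(max(date) - min(date)) + 1L,
      .groups = "drop") |>
    dplyr::mutate(total = blog_posts + comments) |>
    dplyr::arrange(dplyr::desc(total), user_id) |>
    head(n)
  out$rank <- seq_len(nrow(out))
  out[, c("rank", "user_id", "blog_posts", "comments",
          "distinct_days_active", "activity_span_days")]
}

#' Welch two-sample t-test on per-user counts
#'
#' Unequal-variance comparison of means between two samples (e.g.
#' posts-per-user in consecutive years).
#'
#' @param values_a,values_b Numeric samples (each of size >= 2).
#' @return A list with `mean_a`, `mean_b`, `difference`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
welch_mean_test <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each sample needs at least two observations", call. = FALSE)
  }
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    # degenerate constant samples: identical means give p = 1
    same <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    return(list(mean_a = mean(values_a), mean_b = mean(values_b),
                difference = mean(values_b) - mean(values_a),
                ci_low = NA_real_, ci_high = NA_real_,
                p_value = if (same) 1 else 0))
  }
  tt <- t.test(values_b, values_a, var.equal = FALSE)
  list(mean_a = mean(values_a), mean_b = mean(values_b),
       difference = mean(values_b) - mean(values_a),
       ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
       p_value = tt$p.value)
}

#' Cumulative share of items versus share of users
#'
#' Users are sorted by activity (most active first); the curve gives, for
#' each prefix of users, the cumulative share of the year's items they
#' contributed. Monotone nondecreasing, concave, ending at (1, 1); a
#' single dominant user makes it jump towards 1 immediately.
#'
#' @param s An [interaction_set].
#' @param year Calendar year.
#' @return A tibble with `user_frac`, `item_frac`, `user_id` (in rank
#'   order).
#' @export
cumulative_activity_curve <- function(s, year) {
  stopifnot(inherits(s, "interaction_set"))
  items <- s$items
  tz <- attr_tz(items$timestamp)
  yrs <- format(as.Date(items$timestamp, tz = tz), "%Y")
  yr_items <- items[yrs == as.character(year), , drop = FALSE]
  if (nrow(yr_items) == 0) stop("no items in year ", year, call. = FALSE)
  counts <- sort(table(yr_items$user_id), decreasing = TRUE)
  k <- length(counts)
  tibble::tibble(
    user_frac = seq_len(k) / k,
    item_frac = cumsum(as.numeric(counts)) / sum(counts),
    user_id = names(counts))
}
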