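#' Build per-user activity timelines
#'
#' Collapses an interaction set to one timeline per user: the date of
#' first activity (and of the first blog post) over the *full* available
#' history, plus daily item counts over the analysis set. When a separate
#' historic set is supplied, first-activity dates use it, so users who
#' were already active before the analysis period are not mistaken for
#' new arrivals.
#'
#' @param s The analysis-period [interaction_set].
#' @param history Optional [interaction_set] covering the full history
#'   (a superset of, or disjoint prefix to, `s`). When absent, first
#'   activity is inferred from `s` alone and flagged.
#' @return An object of class `user_timelines`: a list with
#'   `users` (tibble: `user_id`, `first_activity_date`, `first_post_date`
#'   — `NA` for users who never posted — `total_items`,
#'   `first_from_history`) and `daily` (tibble: `user_id`, `date`, `n`,
#'   from `s` only).
#' @export
build_timelines <- function(s, history = NULL) {
  stopifnot(inherits(s, "interaction_set"))
  items <- s$items
  tz <- attr_tz(items$timestamp)
  daily <- items |>
    dplyr::mutate(date = as.Date(timestamp, tz = tz)) |>
    dplyr::count(user_id, date, name = "n") |>
    dplyr::arrange(user_id, date)

  all_items <- items
  from_history <- FALSE
  if (!is.null(history)) {
    stopifnot(inherits(history, "interaction_set"))
    extra <- history$items[!history$items$item_id %in% items$item_id, ,
                           drop = FALSE]
    all_items <- dplyr::bind_rows(items, extra)
    from_history <- TRUE
  }
  all_items$date <- as.Date(all_items$timestamp, tz = tz)
  firsts <- all_items |>
    dplyr::group_by(user_id) |>
    dplyr::summarise(
      first_activity_date = min(date),
      first_post_date = if (any(kind == "post")) min(date[kind == "post"])
                        else as.Date(NA),
      .groups = "drop")
  totals <- daily |>
    dplyr::group_by(user_id) |>
    dplyr::summarise(total_items = sum(n), .groups = "drop")
  users <- dplyr::inner_join(firsts, totals, by = "user_id") |>
    dplyr::mutate(first_from_history = from_history) |>
    dplyr::arrange(user_id)
  structure(list(users = users, daily = daily), class = "user_timelines")
}

#' @export
print.user_timelines <- function(x, ...) {
  cat(sprintf("<user_timelines> %d users, %d user-days, %d items\n",
              nrow(x$users), nrow(x$daily), sum(x$daily$n)))
  invisible(x)
}

#' Maximum item count in any rolling window within a calendar year
#'
#' The window statistic behind the engagement thresholds: the maximum,
#' over every `window_days`-day window lying wholly inside the calendar
#' year, of the user's item count in the window. Confining windows to the
#' year mirrors the annual classification design (a window may not span
#' New Year). Returns 0 when the user has no activity that year.
#'
#' @param dates Dates with activity (one per active day).
#' @param counts Item counts for those dates.
#' @param year Calendar year.
#' @param window_days Window length in days (default 90, i.e. the rolling
#'   "three month" window).
#' @return Integer window maximum.
#' @export
window_max <- function(dates, counts, year, window_days = 90) {
  stopifnot(window_days >= 1, length(dates) == length(counts))
  y0 <- as.Date(sprintf("%d-01-01", year))
  y1 <- as.Date(sprintf("%d-12-31", year))
  n_days <- as.integer(y1 - y0) + 1L
  window_days <- min(window_days, n_days)
  keep <- dates >= y0 & dates <= y1
  if (!any(keep)) return(0L)
  v <- integer(n_days)
  pos <- as.integer(dates[keep] - y0) + 1L
  v[pos] <- v[pos] + as.integer(counts[keep])
  cs <- c(0L, cumsum(v))
  starts <- seq_len(n_days - window_days + 1L)
  max(cs[starts + window_days] - cs[starts])
}

#' Classify active users into engagement groups for a calendar year
#'
#' Users with at least one item in the year are assigned exactly one
#' group from their rolling-window maximum: highly engaged (`HEU`) if any
#' `window_days`-day window holds at least `heu_min` items (an average of
#' two or more items per day over 90 days at the defaults), minimally
#' engaged (`MEU`) if no window holds more than `meu_max` items — which
#' tolerates multiple fleeting spells, e.g. two posts in April and two
#' more in August — and `OTHER` in between. Users with no items that year
#' are excluded.
#'
#' @param timelines A [build_timelines()] result.
#' @param year Calendar year to classify.
#' @param heu_min,meu_max,window_days Thresholds (defaults 180 / 2 / 90);
#'   `heu_min` must exceed `meu_max` so the groups cannot overlap.
#' @return An object of class `engagement_classification`: a list with
#'   `year`, `thresholds`, and `users` (tibble: `user_id`, `annual_total`,
#'   `window_max`, `group` factor with levels HEU/OTHER/MEU).
#' @export
classify_engagement <- function(timelines, year, heu_min = 180, meu_max = 2,
                                window_days = 90) {
  stopifnot(inherits(timelines, "user_timelines"),
            heu_min > meu_max, meu_max >= 0, window_days >= 1)
  y0 <- as.Date(sprintf("%d-01-01", year))
  y1 <- as.Date(sprintf("%d-12-31", year))
  daily <- timelines$daily[timelines$daily$date >= y0 &
                             timelines$daily$date <= y1, , drop = FALSE]
  if (nrow(daily) == 0) {
    users <- tibble::tibble(user_id = character(), annual_total = integer(),
                            window_max = integer(),
                            group = factor(character(),
                                           levels = c("HEU", "OTHER", "MEU")))
  } else {
    per_user <- split(daily, daily$user_id)
    wmax <- vapply(per_user, function(d) {
      window_max(d$date, d$n, year, window_days)
    }, integer(1))
    users <- tibble::tibble(
      user_id = names(per_user),
      annual_total = vapply(per_user, function(d) sum(d$n), numeric(1)),
      window_max = unname(wmax))
    users$group <- factor(
      ifelse(users$window_max >= heu_min, "HEU",
             ifelse(users$window_max <= meu_max, "MEU", "OTHER")),
      levels = c("HEU", "OTHER", "MEU"))
    users <- dplyr::arrange(users, user_id)
  }
  structure(list(year = as.integer(year),
                 thresholds = list(heu_min = heu_min, meu_max = meu_max,
                                   window_days = window_days),
                 users = users),
            class = "engagement_classification")
}

#' @export
print.engagement_classification <- function(x, ...) {
  tab <- table(x$users$group)
  cat(sprintf(
    "<engagement_classification> %d: %d active users (HEU %d, OTHER %d, MEU %d)\n",
    x$year, nrow(x$users), tab[["HEU"]], tab[["OTHER"]], tab[["MEU"]]))
  cat(sprintf("  thresholds: HEU >= %d, MEU <= %d items per %d-day window\n",
              x$thresholds$heu_min, x$thresholds$meu_max,
              x$thresholds$window_days))
  invisible(x)
}

#' Group sizes and item-contribution shares with bootstrap intervals
#'
#' For each engagement group: the number of users, the share of active
#' users, and the share of the year's items contributed, with a 95%
#' percentile-bootstrap interval obtained by resampling users with
#' replacement (each resample recomputes group and total item counts from
#' the sampled users' items; classification labels stay fixed). Groups
#' absent from the year get share 0 with a degenerate [0, 0] interval.
#'
#' @param cls An [classify_engagement()] result.
#' @param s The [interaction_set] the classification was computed from.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Integer seed for the resampling.
#' @return A tibble with one row per group: `group`, `n_users`,
#'   `share_users`, `share_items`, `ci_low`, `ci_high`, `n_boot`, `seed`.
#' @export
contribution_shares <- function(cls, s, n_boot = 2000, seed = 1) {
  stopifnot(inherits(cls, "engagement_classification"),
            inherits(s, "interaction_set"), n_boot >= 1)
  tz <- attr_tz(s$items$timestamp)
  yrs <- as.integer(format(as.Date(s$items$timestamp, tz = tz), "%Y"))
  in_year <- s$items[yrs == cls$year, , drop = FALSE]
  per_user <- table(in_year$user_id)
  u <- cls$users
  u$items <- as.integer(per_user[u$user_id])
  u$items[is.na(u$items)] <- 0L
  total <- sum(u$items)
  n_active <- nrow(u)
  groups <- levels(u$group)

  point <- vapply(groups, function(g) {
    if (total == 0) 0 else sum(u$items[u$group == g]) / total
  }, numeric(1))

  boot_mat <- matrix(NA_real_, nrow = n_boot, ncol = length(groups),
                     dimnames = list(NULL, groups))
  if (n_active > 0) {
    with_sim_seed(as.integer(seed), {
      gi <- as.integer(u$group)
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n_active, n_active, replace = TRUE)
        tot_b <- sum(u$items[idx])
        gsum <- vapply(seq_along(groups), function(k) {
          sum(u$items[idx][gi[idx] == k])
        }, numeric(1))
        boot_mat[b, ] <- if (tot_b == 0) rep(0, length(groups))
                         else gsum / tot_b
      }
    })
  }

  out <- tibble::tibble(
    group = factor(groups, levels = groups),
    n_users = unname(vapply(groups, function(g) sum(u$group == g),
                            integer(1))),
    share_users = if (n_active == 0) rep(0, length(groups))
                  else unname(vapply(groups, function(g) mean(u$group == g),
                                     numeric(1))),
    share_items = unname(point),
    ci_low = NA_real_, ci_high = NA_real_,
    n_boot = as.integer(n_boot), seed = as.integer(seed))
  for (k in seq_along(groups)) {
    if (out$n_users[k] == 0 || n_active == 0) {
      out$ci_low[k] <- 0
      out$ci_high[k] <- 0
    } else {
      qs <- quantile(boot_mat[, k], c(0.025, 0.975), names = FALSE)
      out$ci_low[k] <- qs[1]
      out$ci_high[k] <- qs[2]
    }
  }
  out
}

#' Year-over-year engagement group dynamics
#'
#' For each group: size in each year, percent growth, the overlap (users
#' in the group in both years), and how many of the first year's members
#' were active at all in the second year.
#'
#' @param cls_a,cls_b Classifications for consecutive years
#'   (`cls_a$year < cls_b$year`).
#' @return A tibble with one row per group: `group`, `n_a`, `n_b`,
#'   `growth_pct` (`NA` when the first-year count is 0), `overlap`,
#'   `active_in_b`.
#' @export
group_dynamics <- function(cls_a, cls_b) {
  stopifnot(inherits(cls_a, "engagement_classification"),
            inherits(cls_b, "engagement_classification"),
            cls_a$year < cls_b$year)
  groups <- levels(cls_a$users$group)
  rows <- lapply(groups, function(g) {
    ua <- cls_a$users$user_id[cls_a$users$group == g]
    ub <- cls_b$users$user_id[cls_b$users$group == g]
    tibble::tibble(
      group = g,
      n_a = length(ua), n_b = length(ub),
      growth_pct = if (length(ua) == 0) NA_real_
                   else 100 * (length(ub) - length(ua)) / length(ua),
      overlap = length(intersect(ua, ub)),
      active_in_b = sum(ua %in% cls_b$users$user_id))
  })
  out <- dplyr::bind_rows(rows)
  out$group <- factor(out$group, levels = groups)
  out
}

#' Two-sample proportion z-test
#'
#' Standard large-sample comparison of two proportions: the difference
#' `x2/n2 - x1/n1` with an unpooled Wald 95% confidence interval and a
#' two-sided p-value from the pooled z statistic.
#'
#' @param x1,n1 Successes and trials in the first sample.
#' @param x2,n2 Successes and trials in the second sample.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `p1`, `p2`, `difference` (p2 - p1), `ci_low`,
#'   `ci_high`, `z`, `p_value`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2, conf_level = 0.95) {
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive", call. = FALSE)
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("successes must lie in [0, n]", call. = FALSE)
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  diff <- p2 - p1
  zq <- qnorm(1 - (1 - conf_level) / 2)
  se_unpooled <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  pp <- (x1 + x2) / (n1 + n2)
  se_pooled <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se_pooled == 0) 0 else diff / se_pooled
  list(p1 = p1, p2 = p2, difference = diff,
       ci_low = diff - zq * se_unpooled,
       ci_high = diff + zq * se_unpooled,
       z = z, p_value = 2 * pnorm(-abs(z)))
}
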