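#' Early-activity feature vectors for first-time users
#'
#' One vector per cohort user, computed over the user's first calendar
#' date of activity (`first_day`) or the first date plus six following
#' calendar days (`first_week`). Candidate predictors of subsequent
#' disengagement: posts made, comments made (on own or others' posts),
#' the share of the user's items that are comments, distinct active days
#' (first week only; identically 1 for the first day), comments received
#' from other users on the user's window posts (within the window),
#' the mean number of distinct other commenters per window post, and the
#' total word count of the user's window items.
#'
#' @param s An [interaction_set] (cleaned analysis set).
#' @param cohort A data frame with `user_id` and `first_activity_date`
#'   (e.g. a filtered `timelines$users`).
#' @param window `"first_day"` or `"first_week"`.
#' @return A tibble with `user_id`, `window`, `n_posts`,
#'   `n_comments_made`, `pct_comments`, `n_distinct_active_days`,
#'   `n_comments_received`, `mean_distinct_commenters_per_post`,
#'   `total_words`.
#' @export
extract_features <- function(s, cohort,
                             window = c("first_day", "first_week")) {
  stopifnot(inherits(s, "interaction_set"))
  window <- match.arg(window)
  span <- if (window == "first_day") 0L else 6L
  cohort <- tibble::as_tibble(cohort)
  stopifnot(all(c("user_id", "first_activity_date") %in% names(cohort)))

  items <- s$items
  tz <- attr_tz(items$timestamp)
  items$date <- as.Date(items$timestamp, tz = tz)
  win <- tibble::tibble(user_id = as.character(cohort$user_id),
                        d0 = as.Date(cohort$first_activity_date))
  win$d1 <- win$d0 + span

  own <- items |>
    dplyr::inner_join(win, by = "user_id") |>
    dplyr::filter(date >= d0, date <= d1)
  own_stats <- own |>
    dplyr::group_by(user_id) |>
    dplyr::summarise(
      n_posts = sum(kind == "post"),
      n_comments_made = sum(kind == "comment"),
      n_distinct_active_days = length(unique(date)),
      total_words = sum(word_count, na.rm = TRUE),
      .groups = "drop")

  # comments received: by other users, within the window, on posts the
  # user made within the window
  posts_win <- own[own$kind == "post",
                   c("item_id", "user_id", "d0", "d1"), drop = FALSE]
  names(posts_win) <- c("post_id", "owner", "d0", "d1")
  recv <- items[items$kind == "comment", c("thread_id", "user_id", "date"),
                drop = FALSE] |>
    dplyr::inner_join(posts_win, by = c("thread_id" = "post_id")) |>
    dplyr::filter(user_id != owner, date >= d0, date <= d1)
  recv_per_post <- recv |>
    dplyr::group_by(thread_id, owner) |>
    dplyr::summarise(n_recv = dplyr::n(),
                     n_commenters = length(unique(user_id)),
                     .groups = "drop")
  post_cov <- posts_win |>
    dplyr::left_join(recv_per_post,
                     by = c("post_id" = "thread_id", "owner")) |>
    dplyr::mutate(n_recv = ifelse(is.na(n_recv), 0L, n_recv),
                  n_commenters = ifelse(is.na(n_commenters), 0L,
                                        n_commenters)) |>
    dplyr::group_by(owner) |>
    dplyr::summarise(n_comments_received = sum(n_recv),
                     mean_distinct_commenters_per_post = mean(n_commenters),
                     .groups = "drop")

  out <- win |>
    dplyr::left_join(own_stats, by = "user_id") |>
    dplyr::left_join(post_cov, by = c("user_id" = "owner"))
  zero <- function(x) ifelse(is.na(x), 0, x)
  tibble::tibble(
    user_id = out$user_id,
    window = window,
    n_posts = as.integer(zero(out$n_posts)),
    n_comments_made = as.integer(zero(out$n_comments_made)),
    pct_comments = ifelse(zero(out$n_posts) + zero(out$n_comments_made) == 0,
                          0, zero(out$n_comments_made) /
                            (zero(out$n_posts) + zero(out$n_comments_made))),
    n_distinct_active_days = as.integer(zero(out$n_distinct_active_days)),
    n_comments_received = as.integer(zero(out$n_comments_received)),
    mean_distinct_commenters_per_post =
      zero(out$mean_distinct_commenters_per_post),
    total_words = as.integer(zero(out$total_words)))
}

#' Label minimally-engaged outcome over a 90-day follow-up
#'
#' A cohort user is labelled a minimally engaged user (MEU) when they
#' contribute at most `meu_max` items in the 90 days starting at their
#' first activity date (`[start, start + 89]`). The supplied set must
#' extend at least 90 days past every start date.
#'
#' @param s An [interaction_set] covering the follow-up horizon.
#' @param cohort A data frame with `user_id` and `first_activity_date`.
#' @param follow_up_days Follow-up horizon (default 90).
#' @param meu_max Item threshold (default 2).
#' @return A tibble with `user_id`, `start_date`, `n_followup_items`,
#'   `label` (logical, `TRUE` = MEU).
#' @export
label_meu <- function(s, cohort, follow_up_days = 90, meu_max = 2) {
  stopifnot(inherits(s, "interaction_set"))
  cohort <- tibble::as_tibble(cohort)
  start <- as.Date(cohort$first_activity_date)
  horizon <- start + follow_up_days - 1
  short <- horizon > s$period_end
  if (any(short)) {
    stop("insufficient follow-up (needs ", follow_up_days,
         " days) for user(s): ",
         paste(head(cohort$user_id[short], 10), collapse = ", "),
         call. = FALSE)
  }
  items <- s$items
  tz <- attr_tz(items$timestamp)
  items$date <- as.Date(items$timestamp, tz = tz)
  win <- tibble::tibble(user_id = as.character(cohort$user_id),
                        start = start, horizon = horizon)
  fu <- items |>
    dplyr::inner_join(win, by = "user_id") |>
    dplyr::filter(date >= start, date <= horizon) |>
    dplyr::count(user_id, name = "n_fu")
  n_fu <- fu$n_fu[match(win$user_id, fu$user_id)]
  n_fu[is.na(n_fu)] <- 0L
  tibble::tibble(user_id = win$user_id, start_date = start,
                 n_followup_items = as.integer(n_fu),
                 label = n_fu <= meu_max)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, with ties counted one half — computed from the rank
#' statistic, so it equals exhaustive pair enumeration exactly.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) outcome labels.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores),
            !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute AUROC", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit an early-disengagement logistic model with holdout evaluation
#'
#' Plain maximum-likelihood logistic regression (no regularisation) of
#' MEU outcome on early-activity features, fitted on a seeded simple
#' random `train_frac` sample of users and evaluated on the remaining
#' holdout. The retained variable sets are fixed per window — first day:
#' posts, comments made, share of comments, total words; first week:
#' posts and comments made — and can be overridden with `variables` or
#' replaced by an exhaustive AUROC-maximising search over the candidate
#' set (`search = TRUE`, off by default). A user is predicted MEU when
#' the fitted score strictly exceeds `cut` (a score of exactly `cut`
#' counts as non-MEU).
#'
#' @param features An [extract_features()] tibble.
#' @param labels A [label_meu()] tibble (matched by `user_id`).
#' @param train_frac Training fraction (default 0.70).
#' @param seed Seed for the random split.
#' @param cut Score cut-point (default 0.5).
#' @param variables Optional character vector of feature columns.
#' @param search If `TRUE`, pick the candidate subset maximising holdout
#'   AUROC instead of the fixed set.
#' @return A list of class `meu_model`: `fit` (the `glm`), `window`,
#'   `variables`, `separation` (logical: fit flagged for complete or
#'   quasi separation), and `report` (class `discrimination_report`:
#'   `n_train`, `n_test`, `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `auroc`, `cut`, `seed`).
#' @export
fit_meu_model <- function(features, labels, train_frac = 0.70, seed = 1,
                          cut = 0.5, variables = NULL, search = FALSE) {
  df <- dplyr::inner_join(features, labels[, c("user_id", "label")],
                          by = "user_id")
  if (nrow(df) < 2) stop("need at least two users", call. = FALSE)
  window <- df$window[1]
  fixed_vars <- if (identical(window, "first_day")) {
    c("n_posts", "n_comments_made", "pct_comments", "total_words")
  } else {
    c("n_posts", "n_comments_made")
  }
  candidates <- c("n_posts", "n_comments_made", "pct_comments",
                  "n_comments_received", "mean_distinct_commenters_per_post",
                  "total_words")
  if (identical(window, "first_week")) {
    candidates <- c(candidates, "n_distinct_active_days")
  }

  n <- nrow(df)
  idx_train <- with_sim_seed(as.integer(seed), {
    sample.int(n, size = floor(train_frac * n))
  })
  train <- df[idx_train, , drop = FALSE]
  test <- df[-idx_train, , drop = FALSE]
  if (length(unique(train$label)) < 2) {
    stop("both classes must be present in the training data", call. = FALSE)
  }

  fit_one <- function(vars) {
    fml <- stats::as.formula(paste("label ~", paste(vars, collapse = " + ")))
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(fml, data = train, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
            grepl("did not converge", conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    list(fit = fit, separation = sep)
  }

  vars <- variables %||% fixed_vars
  if (search) {
    best <- NULL
    best_auc <- -Inf
    for (k in seq_along(candidates)) {
      for (set in utils::combn(candidates, k, simplify = FALSE)) {
        f <- fit_one(set)
        a <- auroc(predict(f$fit, newdata = test, type = "response"),
                   test$label)
        if (a > best_auc) {
          best_auc <- a
          best <- set
        }
      }
    }
    vars <- best
  }
  fitted <- fit_one(vars)
  scores <- predict(fitted$fit, newdata = test, type = "response")
  pred <- scores > cut
  tp <- sum(pred & test$label)
  fp <- sum(pred & !test$label)
  tn <- sum(!pred & !test$label)
  fn <- sum(!pred & test$label)
  report <- structure(
    list(window = window, variables = vars,
         n_train = nrow(train), n_test = nrow(test),
         tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
         specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
         auroc = auroc(scores, test$label),
         cut = cut, seed = as.integer(seed)),
    class = "discrimination_report")
  structure(list(fit = fitted$fit, window = window, variables = vars,
                 separation = fitted$separation,
                 train_user_ids = train$user_id,
                 test_user_ids = test$user_id,
                 report = report),
            class = "meu_model")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("<discrimination_report> %s model (%s)\n", x$window,
              paste(x$variables, collapse = " + ")))
  cat(sprintf("  holdout n = %d (train %d); cut %.2f\n", x$n_test,
              x$n_train, x$cut))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, AUROC %.3f\n",
              x$sensitivity, x$specificity, x$auroc))
  cat(sprintf("  confusion: TP %d, FP %d, TN %d, FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' @export
print.meu_model <- function(x, ...) {
  print(x$report)
  if (x$separation) cat("  note: fit flagged for (quasi-)separation\n")
  invisible(x)
}
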