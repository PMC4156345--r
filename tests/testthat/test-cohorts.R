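test_that("timelines aggregate daily activity and locate first dates", {
  s <- make_set(
    list("p1", "u1", "2012-02-01 10:00:00", "post", "p1", "a"),
    list("c1", "u1", "2012-02-01 12:00:00", "comment", "p1", "b"),
    list("c2", "u1", "2012-02-03 12:00:00", "comment", "p1", "c"),
    list("p2", "u1", "2012-03-01 12:00:00", "post", "p2", "d"),
    list("p3", "u2", "2012-02-02 09:00:00", "post", "p3", "e")
  )
  tl <- build_timelines(s)
  u1 <- tl$daily[tl$daily$user_id == "u1", ]
  expect_equal(nrow(u1), 3L)
  expect_equal(sum(u1$n), 4L)
  expect_equal(sum(tl$daily$n), n_items(s))
  expect_equal(tl$users$first_activity_date[tl$users$user_id == "u1"],
               as.Date("2012-02-01"))
  expect_false(any(tl$users$first_from_history))
})

test_that("historic data moves first activity before the analysis period", {
  hist <- make_set(
    list("h1", "u1", "2009-06-01 10:00:00", "post", "h1", "old"))
  s <- make_set(
    list("p1", "u1", "2012-02-01 10:00:00", "post", "p1", "a"))
  tl <- build_timelines(s, history = hist)
  expect_equal(tl$users$first_activity_date, as.Date("2009-06-01"))
  expect_lt(tl$users$first_activity_date, s$period_start)
  expect_true(all(tl$users$first_from_history))
  # daily counts still cover the analysis set only
  expect_equal(sum(tl$daily$n), 1L)
})

test_that("rolling window maximum handles the threshold arithmetic", {
  # two items per day for 90 consecutive days reaches exactly 180
  dates <- as.Date("2012-03-01") + 0:89
  expect_equal(window_max(dates, rep(2L, 90), 2012, 90), 180L)
  # an empty year gives zero
  expect_equal(window_max(dates, rep(2L, 90), 2014, 90), 0L)
  # activity on the year boundary is confined to in-year windows
  expect_equal(window_max(as.Date(c("2011-12-31", "2012-01-01")),
                          c(5L, 3L), 2012, 90), 3L)
})

test_that("window maximum equals the exhaustive all-start-dates scan", {
  set.seed(601)
  for (rep in 1:12) {
    t <- random_timeline(year = 2012, n_events = sample(5:30, 1))
    for (w in c(7, 90, 366)) {
      expect_equal(window_max(t$date, t$n, 2012, w),
                   window_max_oracle(t$date, t$n, 2012, w))
    }
  }
})

test_that("classification reproduces the defining examples", {
  # two posts in April and another two in August: minimally engaged
  s <- make_set(
    list("p1", "u1", "2012-04-02 10:00:00", "post", "p1", "a"),
    list("p2", "u1", "2012-04-03 10:00:00", "post", "p2", "b"),
    list("p3", "u1", "2012-08-02 10:00:00", "post", "p3", "c"),
    list("p4", "u1", "2012-08-03 10:00:00", "post", "p4", "d"),
    # three items inside one window: neither MEU nor HEU
    list("p5", "u2", "2012-04-02 10:00:00", "post", "p5", "e"),
    list("p6", "u2", "2012-04-03 10:00:00", "post", "p6", "f"),
    list("p7", "u2", "2012-04-04 10:00:00", "post", "p7", "g"),
    period_start = "2012-01-01", period_end = "2012-12-31"
  )
  cls <- classify_engagement(build_timelines(s), 2012)
  groups <- setNames(as.character(cls$users$group), cls$users$user_id)
  expect_equal(groups[["u1"]], "MEU")
  expect_equal(groups[["u2"]], "OTHER")
})

test_that("every active user lands in exactly one group", {
  sim <- simulate_network(sim_config(n_users = 250, seed = 17))
  tl <- build_timelines(sim$set)
  for (yr in c(2011, 2012)) {
    cls <- classify_engagement(tl, yr)
    expect_false(anyNA(cls$users$group))
    expect_equal(anyDuplicated(cls$users$user_id), 0L)
    active <- unique(tl$daily$user_id[format(tl$daily$date, "%Y") ==
                                        as.character(yr)])
    expect_setequal(cls$users$user_id, active)
    # HEU and MEU criteria agree with the window statistic
    expect_true(all((cls$users$group == "HEU") ==
                      (cls$users$window_max >= 180)))
    expect_true(all((cls$users$group == "MEU") ==
                      (cls$users$window_max <= 2)))
  }
})

test_that("adding activity never demotes HEU nor promotes to MEU", {
  set.seed(602)
  for (rep in 1:8) {
    t <- random_timeline(year = 2012, n_events = 15)
    before <- window_max(t$date, t$n, 2012)
    extra <- random_timeline(year = 2012, n_events = 5)
    both <- dplyr::bind_rows(t, extra) |>
      dplyr::group_by(date) |>
      dplyr::summarise(n = sum(n), .groups = "drop")
    after <- window_max(both$date, both$n, 2012)
    expect_gte(after, before)
  }
})

test_that("contribution shares match hand-countable fixtures", {
  # one group only: share 1 with degenerate interval
  s <- make_set(
    list("p1", "u1", "2012-04-02 10:00:00", "post", "p1", "a"),
    list("p2", "u2", "2012-04-03 10:00:00", "post", "p2", "b"),
    period_start = "2012-01-01", period_end = "2012-12-31")
  cls <- classify_engagement(build_timelines(s), 2012)
  con <- contribution_shares(cls, s, n_boot = 100, seed = 1)
  meu <- con[con$group == "MEU", ]
  expect_equal(meu$share_items, 1)
  expect_equal(c(meu$ci_low, meu$ci_high), c(1, 1))
  expect_equal(con$share_items[con$group == "HEU"], 0)
  expect_equal(con$ci_high[con$group == "HEU"], 0)
  expect_equal(sum(con$share_items), 1)

  # 5 users, 50 items; u1 holds 10 of them in a single burst, the other
  # four spread 10 each across the year, so meu_max = 3 isolates u1 as
  # the sole OTHER user with a 10-of-50 item share
  rows <- list()
  for (i in 1:10) {
    rows[[length(rows) + 1]] <- list(
      sprintf("u1_%02d", i), "u1",
      sprintf("2012-06-%02d 10:00:00", i), "post",
      sprintf("u1_%02d", i), paste("burst", i))
  }
  for (u in c("u2", "u3", "u4", "u5")) {
    for (i in 1:10) {
      d <- as.Date("2012-01-10") + (i - 1) * 36
      rows[[length(rows) + 1]] <- list(
        sprintf("%s_%02d", u, i), u,
        paste(d, "10:00:00"), "post",
        sprintf("%s_%02d", u, i), paste(u, i))
    }
  }
  s2 <- do.call(make_set, c(rows, list(period_start = "2012-01-01",
                                       period_end = "2012-12-31")))
  cls2 <- classify_engagement(build_timelines(s2), 2012,
                              heu_min = 180, meu_max = 3)
  con2 <- contribution_shares(cls2, s2, n_boot = 100, seed = 1)
  other <- con2[con2$group == "OTHER", ]
  expect_equal(other$n_users, 1L)
  expect_equal(other$share_users, 1 / 5)
  expect_equal(other$share_items, 10 / 50)
  expect_equal(con2$share_items[con2$group == "MEU"], 40 / 50)
  expect_equal(sum(con2$share_items), 1)
})

test_that("percentile bootstrap brackets its point estimate", {
  set.seed(603)
  inside <- 0
  n_rep <- 500
  for (rep in seq_len(n_rep)) {
    n_u <- 40
    items <- rpois(n_u, 4) + 1
    grp <- sample(c("MEU", "OTHER"), n_u, replace = TRUE, prob = c(.4, .6))
    u <- tibble::tibble(user_id = sprintf("u%02d", seq_len(n_u)),
                        items = items, group = grp)
    share <- sum(u$items[u$group == "MEU"]) / sum(u$items)
    boots <- replicate(200, {
      idx <- sample.int(n_u, n_u, replace = TRUE)
      sum(u$items[idx][u$group[idx] == "MEU"]) / sum(u$items[idx])
    })
    qs <- quantile(boots, c(.025, .975), names = FALSE)
    if (share >= qs[1] && share <= qs[2]) inside <- inside + 1
  }
  expect_gte(inside / n_rep, 0.94)
})

test_that("group dynamics report growth, overlap and persistence", {
  mk_cls <- function(year, ids_by_group) {
    users <- dplyr::bind_rows(lapply(names(ids_by_group), function(g) {
      tibble::tibble(user_id = ids_by_group[[g]], annual_total = 1,
                     window_max = 1,
                     group = factor(g, levels = c("HEU", "OTHER", "MEU")))
    }))
    structure(list(year = year,
                   thresholds = list(heu_min = 180, meu_max = 2,
                                     window_days = 90),
                   users = users),
              class = "engagement_classification")
  }
  a <- mk_cls(2011, list(HEU = sprintf("h%02d", 1:33),
                         OTHER = sprintf("o%02d", 1:10)))
  b <- mk_cls(2012, list(HEU = c(sprintf("h%02d", 1:12),
                                 sprintf("g%02d", 1:57)),
                         OTHER = sprintf("h%02d", 13:20)))
  dyn <- group_dynamics(a, b)
  heu <- dyn[dyn$group == "HEU", ]
  expect_equal(heu$n_a, 33L)
  expect_equal(heu$n_b, 69L)
  expect_equal(round(heu$growth_pct), 109)
  expect_equal(heu$overlap, 12L)
  # 12 stayed HEU and 8 more were active in OTHER
  expect_equal(heu$active_in_b, 20L)

  same <- group_dynamics(mk_cls(2011, list(HEU = c("a", "b"))),
                         mk_cls(2012, list(HEU = c("a", "b"))))
  expect_equal(same$growth_pct[same$group == "HEU"], 0)
  expect_equal(same$overlap[same$group == "HEU"], 2L)
})

test_that("overlap equals the set-intersection oracle on random cohorts", {
  set.seed(604)
  for (rep in 1:6) {
    sim <- simulate_network(sim_config(n_users = 150, seed = 700 + rep))
    tl <- build_timelines(sim$set)
    a <- classify_engagement(tl, 2011, heu_min = 20, meu_max = 2)
    b <- classify_engagement(tl, 2012, heu_min = 20, meu_max = 2)
    if (nrow(a$users) == 0 || nrow(b$users) == 0) next
    dyn <- group_dynamics(a, b)
    for (g in c("HEU", "OTHER", "MEU")) {
      ia <- a$users$user_id[a$users$group == g]
      ib <- b$users$user_id[b$users$group == g]
      expect_equal(dyn$overlap[dyn$group == g], length(intersect(ia, ib)))
    }
  }
})

test_that("two-proportion z-test matches closed form and the permutation oracle", {
  eq <- two_proportion_test(10, 50, 10, 50)
  expect_equal(eq$difference, 0)
  expect_equal(eq$p_value, 1)

  # the year-over-year highly-engaged share comparison
  tt <- two_proportion_test(33, 1386, 69, 2062)
  expect_equal(tt$difference, 69 / 2062 - 33 / 1386)
  expect_equal(round(100 * tt$difference, 2), 0.97)
  # printed-precision agreement on the interval endpoints
  expect_equal(100 * tt$ci_low, -0.1, tolerance = 0.1)
  expect_equal(round(100 * tt$ci_high, 1), 2.1)
  expect_equal(round(tt$p_value, 2), 0.10)
  # pooled z equals the chi-square statistic of prop.test
  pt <- suppressWarnings(stats::prop.test(c(33, 69), c(1386, 2062),
                                          correct = FALSE))
  expect_equal(tt$z^2, unname(pt$statistic))

  # permutation oracle on small tables (mid-p convention for the
  # discrete permutation distribution)
  set.seed(42)
  tables <- list(c(14, 50, 30, 55), c(20, 100, 35, 120),
                 c(8, 40, 16, 45), c(26, 90, 52, 110))
  for (tb in tables) {
    x1 <- tb[1]; n1 <- tb[2]; x2 <- tb[3]; n2 <- tb[4]
    obs <- abs(x2 / n2 - x1 / n1)
    pool <- c(rep(1, x1 + x2), rep(0, n1 + n2 - x1 - x2))
    perm <- replicate(10000, {
      g <- sample(pool)
      abs(mean(g[(n1 + 1):(n1 + n2)]) - mean(g[1:n1]))
    })
    p_perm <- mean(perm > obs + 1e-12) +
      0.5 * mean(abs(perm - obs) < 1e-12)
    p_z <- two_proportion_test(x1, n1, x2, n2)$p_value
    expect_lt(abs(p_perm - p_z), 0.02)
  }
  expect_error(two_proportion_test(1, 0, 1, 2), "positive")
})
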