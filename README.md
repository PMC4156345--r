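# ocsntools

Engagement analysis for online cessation support networks (OCSNs) —
web communities where people quitting smoking write blog posts and
comment on each other's posts. The package is aimed at researchers and
intervention designers who have an interaction-metadata extract (one row
per post or comment, with user id, timestamp, kind and thread linkage)
and want reproducible answers to three questions:

1. **What does aggregate posting look like over time?** Monthly series of
   first-time posts with exact Poisson intervals; day-of-week activity
   means adjusted for weekly clustering, with holiday weeks excluded.
2. **Who carries the network?** Rolling-window engagement classification
   and the contribution share of each group, with bootstrap intervals.
3. **Can fleeting users be spotted early?** Logistic prediction of
   minimal engagement from first-day / first-week activity, evaluated on
   a holdout sample.

Because real OCSN extracts are rarely shareable, the package ships a
seeded synthetic stream generator with ground truth, so every stage of
the pipeline is testable end to end.

## The statistics at the core

**Engagement groups.** For calendar year *y* and user *u*, let
*W(u) = max over 90-day windows [d, d+89] inside y* of the user's item
count in the window (items = posts + comments). A user active in *y* is a

- **Highly Engaged User (HEU)** if *W(u) ≥ 180* — an average of two or
  more items per day sustained over three months;
- **Minimally Engaged User (MEU)** if *W(u) ≤ 2* — which tolerates
  multiple fleeting "spells" (e.g. two posts in April, two in August);
- **OTHER** in between.

The rolling window (rather than fixed calendar quarters) avoids
penalising users who start mid-year. Group item shares come with 95%
percentile-bootstrap intervals from resampling users with replacement.

**Day-of-week model.** Total daily items are regressed on a saturated
weekday factor with identity link, Poisson working variance and an
independence working correlation; variance is estimated by a
cluster-robust sandwich over ISO weeks. Under this specification the
point estimates are exactly the per-weekday arithmetic means, and the
weekly clustering only widens the uncertainty. Weeks containing a public
holiday or awareness day falling Monday–Friday are excluded first (a New
Zealand calendar for 2011–2012 including World Smokefree Day is bundled;
supply your own via `read_holidays()`).

**Early prediction.** A user is labelled MEU when they contribute at most
2 items in the 90 days after their first activity. Logistic models score
new users from first-day features (posts, comments made, share of
comments, total words) or first-week features (posts, comments made);
fitting uses a random 70% of users, and sensitivity, specificity and
AUROC (Mann–Whitney form) are reported on the 30% holdout at a 0.5 cut.

**Cleaning.** Scraped extracts carry two artifacts: accidental verbatim
re-submissions and a staff account's comments. `clean_pipeline()`
removes within-thread exact-text duplicates (SHA-1 fingerprint of the
raw text, earliest copy kept) and all items by listed staff accounts,
with a conservation-checked report.

## Worked example

```r
library(ocsntools)

cfg <- sim_config(n_users = 400, seed = 2014)   # two years, 2011-2012
sim <- simulate_network(cfg)                    # clean synthetic stream
raw <- inject_artifacts(sim$set, cfg)           # add duplicates + staff
res <- clean_pipeline(raw$set, staff_ids = cfg$staff_user_id)
res$report
#> <cleaning_report> 26235 raw - 115 duplicates - 255 staff = 25865 items

tl  <- build_timelines(res$set)
cls <- classify_engagement(tl, year = 2012)
cls
#> <engagement_classification> 2012: 314 active users (HEU 14, OTHER 172, MEU 128)
#>   thresholds: HEU >= 180, MEU <= 2 items per 90-day window

contribution_shares(cls, res$set, n_boot = 2000, seed = 1)
#> # A tibble: 3 × 8
#>   group n_users share_users share_items  ci_low ci_high n_boot  seed
#>   <fct>   <int>       <dbl>       <dbl>   <dbl>   <dbl>  <int> <int>
#> 1 HEU        14      0.0446     0.584   0.397    0.700    2000     1
#> 2 OTHER     172      0.548      0.408   0.293    0.591    2000     1
#> 3 MEU       128      0.408      0.00865 0.00605  0.0133   2000     1
```

4% of users are highly engaged yet contribute 58% (CI 40–70%) of all
items, while the 41% of minimally engaged users contribute under 1.5% —
the heavy-tailed structure typical of support communities.

```r
ds  <- exclude_event_weeks(daily_count_series(res$set), read_holidays())
weekday_adjusted_means(ds)
#> <weekday_fit> 90 weeks (16 excluded)
#> # A tibble: 7 × 7
#>   weekday estimate ci_low ci_high diff_vs_monday        z   p_value
#>   <fct>      <dbl>  <dbl>   <dbl>          <dbl>    <dbl>     <dbl>
#> 1 Mon         40.4   36.2    44.7         0        0      NA
#> 5 Fri         34.3   30.9    37.7        -6.18    -4.43    9.45e- 6
#> 6 Sat         23.5   20.8    26.2       -17.0    -11.9     7.33e-33
#> 7 Sun         23.6   20.9    26.3       -16.9    -10.7     1.19e-26
```

Activity is high on working days, dips on Friday and collapses on the
weekend; the Saturday/Sunday contrasts against Monday are strongly
significant under week-cluster-robust errors.

```r
cohort <- subset(tl$users, first_activity_date >= as.Date("2011-10-01") &
                           first_activity_date <= as.Date("2012-09-30"),
                 select = c(user_id, first_activity_date))
model <- fit_meu_model(extract_features(res$set, cohort, "first_week"),
                       label_meu(res$set, cohort), seed = 1)
model
#> <discrimination_report> first_week model (n_posts + n_comments_made)
#>   holdout n = 70 (train 161); cut 0.50
#>   sensitivity 0.812, specificity 0.921, AUROC 0.961
```

First-week post and comment counts alone identify most soon-to-disengage
users on the holdout sample.

A thin command-line driver with `simulate`, `clean`, `classify`,
`temporal`, `predict` and `report` subcommands is installed at
`inst/cli/ocsn.R` (see its header for usage).

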