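---
title: "Methods: engagement analysis of online cessation support network activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: engagement analysis of online cessation support network activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and design choices
behind `ocsntools`, in the spirit of a statistical methods appendix.
Nothing here states an empirical result beyond what the package's test
suite and `scripts/acceptance.R` themselves compute.

## Data model

An *interaction* is a blog post or a comment, carrying an opaque item
id, user id, a naive local timestamp (a single local clock; the package
performs no timezone arithmetic), a kind, the id of its thread's root
post (a post is its own root), and optionally the text. When text is
present the package derives a whitespace-token word count and a SHA-1
fingerprint of the exact bytes. An `interaction_set` couples the items
with the closed calendar interval they cover. Comments whose root is
missing from the set are retained and listed as orphans rather than
dropped: an extract truncated at a period boundary routinely loses
roots, and silently discarding replies would bias per-user counts.

## Cleaning

Two artifacts of scraped extracts are removed, in a fixed order:

1. **Within-thread exact-text duplicates.** Items of a thread that share
   a text fingerprint are collapsed to a single survivor. Duplicates are
   defined *within-thread only*: the same short phrase ("congrats!")
   legitimately recurs across threads, while an identical text twice in
   one thread is almost surely an accidental double submission. The text
   is hashed exactly as stored — no case folding or whitespace
   normalisation — since any normalisation would manufacture duplicates
   the platform never saw. The survivor is the earliest copy, with ties
   broken by the smaller item id; which copy survives is immaterial to
   every downstream count, but a deterministic rule keeps the pipeline
   reproducible and order-independent.
2. **Staff-account exclusion.** All items authored by listed staff ids
   are removed, so that analyses cover user-to-user interaction.

The combined report satisfies
`n_raw = n_final + n_duplicates_removed + n_staff_removed`, and the
pipeline is a projection: a second application removes nothing. Both
properties are enforced by tests.

## Engagement classification

For a calendar year, each user active in it (at least one item) receives
the statistic `window_max`: the maximum item count over every 90-day
window lying wholly inside the year, computed from a cumulative sum over
the year's daily counts and verified against a brute-force scan of all
start dates in the tests. Thresholds (configurable, defaults shown):

| parameter     | default | meaning                                     |
|---------------|--------:|---------------------------------------------|
| `window_days` |      90 | rolling "three month" window, advanced daily |
| `heu_min`     |     180 | HEU: some window holds ≥ 180 items (≥ 2/day) |
| `meu_max`     |       2 | MEU: no window holds more than 2 items       |

Design choices that were genuinely open:

- **Rolling window, not calendar quarters.** A fixed-quarter scheme is
  coarser and penalises users who start mid-quarter; the 90-day rolling
  window treats all start dates alike.
- **Windows confined to the year.** Annual classification should not
  credit activity from an adjacent year; the price is that users
  starting in the last two months of a year can never reach the HEU bar
  for that year, which is a property of the definition, not a bug.
- **Active = at least one item that year.** Users with no items are not
  classified for that year (there is no observable distinction between
  a silent registered user and no user at all in this metadata).

Contribution shares are the labelled group's fraction of the year's
items. Uncertainty comes from a percentile bootstrap over *users*
(default 2,000 resamples, mandatory seed): each resample redraws users
with replacement, keeps their fixed classification labels, and recomputes
group and total item counts. User-level (rather than item-level)
resampling respects the clustering of items within users, which is the
dominant source of variance in a heavy-tailed network. "±" figures are
half-widths of these 95% intervals.

## Temporal patterns

**Monthly first-time posts.** A first-time post is the first blog post a
user account ever makes, located over the *full available history* so
that arrivals from before the analysis period are not recounted. Monthly
counts carry exact (Garwood) Poisson intervals from chi-square
quantiles — `[qchisq(.025, 2k)/2, qchisq(.975, 2k+2)/2]`, lower bound 0
at k = 0 — rather than normal approximations, because synthetic or
partial extracts can produce small months where the approximation fails.

**Day-of-week means.** Daily total items are modelled with a saturated
weekday factor, identity link and Poisson working variance, independence
working correlation, and a cluster-robust (sandwich) covariance over
ISO-8601 weeks. Implementation: `glm(quasipoisson(link = "identity"))`
started at the weekday means, with `sandwich::vcovCL(type = "HC0")`
clustered on the week key. Three facts make this the transparent
choice:

- with a saturated one-way design and identity link, the estimating
  equations are solved exactly by the per-weekday arithmetic means
  (asserted to 1e-9 in the tests), so "adjusted mean" means what it
  says;
- for the same reason the per-group working weights cancel from the
  sandwich, so the cluster-robust covariance does not depend on the
  working variance chosen;
- weekly clusters absorb the strong within-week correlation of posting
  levels, and contrasts against Monday are Wald z tests on the robust
  covariance.

Weeks are ISO-8601 (Monday start), matching the Monday-anchored
contrasts. Before fitting, every ISO week containing a calendar event
that falls Monday–Friday is excluded; weekend events exclude nothing,
since they do not perturb the working-week profile. A New Zealand
2011–2012 calendar (national public holidays, observed days, and World
Smokefree Day on 31 May) ships as an editable CSV in `inst/extdata/`.

## Early prediction of minimal engagement

The outcome is MEU status over a 90-day follow-up from the user's first
activity date (their first item's date — registration dates are not in
the metadata). The cohort should be restricted to users whose follow-up
fits inside the observed period; `label_meu()` refuses cohorts with
insufficient follow-up rather than truncating silently.

Windows are calendar-based: *first day* is the first calendar date of
activity, *first week* that date plus six following days. Feature
definitions worth pinning down: comments *received* count only comments
by other users, within the window, on posts the user made within the
window; the mean-distinct-commenters feature averages over the user's
window posts and is 0 for users with no posts; word counts are
whitespace tokens.

Models are plain maximum-likelihood logistic regressions — no
regularisation, matching the sample sizes and the goal of transparent
coefficients. The retained variable sets are fixed (first day: posts,
comments made, share of comments, total words; first week: posts and
comments made); an exhaustive AUROC-maximising subset search over the
candidate list is available behind `search = TRUE` but off by default.
The split is a seeded simple random 70/30 by user, not stratified.
Discrimination is reported on the holdout only: sensitivity and
specificity at a 0.5 score cut (a score of exactly 0.5 counts as
non-MEU, i.e. only scores *above* the cut predict MEU), and AUROC in its
Mann–Whitney form (ties get half credit), which the tests pin to an
all-pairs enumeration oracle and to an independent ROC implementation.
Complete or quasi-separation — common when the fleeting class is well
separated — is flagged on the model object; the holdout report is still
produced from the fitted scores, which remain well defined.

## The synthetic generator

The generator produces streams with the statistical structure the
analysis assumes, plus ground truth, so that classifier recovery and
cleaning inversion can be tested exactly. It is a calibration device,
not a claim about any real network's mechanism.

- **Engagement classes as a finite mixture** (default: 3% `high`, 47%
  `regular`, 50% `fleeting`), not a continuous power law: the simplest
  mechanism that reproduces a heavy-tailed activity distribution while
  giving categorical truth for recovery tests. Per class: mean items
  per active day (4 / 1.2 / 0.3), mean active days (250 / 35 / 1), and
  a decay timescale concentrating active days after arrival
  (300 / 90 / 14 days) — new members are most active right after
  joining, which also makes first-week features informative.
- **Arrivals** follow a 12-weight seasonal profile (January peak after
  New Year resolutions, a May bump around the awareness day, December
  trough) scaled by an annual growth factor (default 1.5 per year,
  mirroring a growing network), with the day uniform within month.
- **Daily emission** is Poisson at the class rate modulated by a
  7-weight weekday profile (working week high, Friday dip, weekend
  low), with at least one item forced on the first active day so every
  simulated user is observable.
- **Threading.** An emission is a post with probability
  `1/(1 + comment_rate)`, otherwise a comment attached to a post drawn
  uniformly from the current and previous three days (falling back to a
  post when the pool is empty, and always timestamped after its root).
  This single mechanism makes total emissions exactly a Poisson
  superposition — which the tests exploit — while delivering
  `comment_rate` comments per post in expectation (default 6, with
  roughly one post in seven, the composition typical of threaded
  support forums).
- **Artifacts.** `inject_artifacts()` appends verbatim re-submissions
  1–60 s later into the same thread (per-item probability, default
  0.004) and one staff reply per post with probability 0.06 under a
  reserved staff id, everything flagged in ground truth. Exact-count
  overrides exist so extracts with a known cleaning arithmetic can be
  constructed. Injected staff texts carry a unique serial token so the
  injection itself can never manufacture accidental duplicates.

What the generator does **not** emulate: message content and semantics,
lurkers (no observable events), commenting-on-comments (threads are
flat, as in the metadata analysed), user-to-user affinity or social
ties, and platform changes over time. Tests passing on synthetic data
therefore validate the *pipeline's arithmetic and inference machinery*,
not any claim about real-network effect sizes.

## Validation design and problem sizes

The test battery pairs every non-trivial operation with an independent
oracle: pairwise text comparison for dedup, an all-start-dates scan for
the window statistic, all-pairs enumeration (and pROC) for AUROC,
per-weekday means for the clustered model, permutation tests (mid-p,
fixed tables) for the proportion and mean comparisons, and generator
ground truth for cleaning inversion and class recovery. Recovery runs
use 2,000 users over one year with arrivals confined to January to
September, so every user has a full 90-day window and follow-up inside
the year — the same reasoning the annual classification applies to
late-year starters. The full-scale cleaning check uses a 133,096-item
base with exactly 549 duplicates and 1,137 staff comments injected;
other property tests use 60–800 simulated users, sizes at which every
targeted property is already sharply testable.

## Known limitations

- Timestamps are treated as one naive local clock; extracts spanning a
  daylight-saving change may place a handful of night-time items on the
  wrong side of midnight.
- The duplicate rule collapses *exact* within-thread repeats only;
  near-duplicates (edited re-submissions) are out of scope, as is any
  cross-thread deduplication.
- Window-confined annual classification cannot award HEU status for
  sustained activity spanning New Year; a user posting heavily from
  November to February may be OTHER in both years.
- The bootstrap keeps classification labels fixed within resamples; it
  quantifies sampling variability of the share, not uncertainty in the
  thresholds themselves.
- With strong class separation the logistic fits sit at the boundary of
  the parameter space (separation); coefficients are then not
  interpretable even though holdout discrimination is.
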