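new_cleaning_report <- function(n_raw, duplicate_item_ids, staff_item_ids) {
  structure(
    list(
      n_raw = as.integer(n_raw),
      n_duplicates_removed = length(duplicate_item_ids),
      n_staff_removed = length(staff_item_ids),
      n_final = as.integer(n_raw) - length(duplicate_item_ids) -
        length(staff_item_ids),
      duplicate_item_ids = as.character(duplicate_item_ids),
      staff_item_ids = as.character(staff_item_ids)
    ),
    class = "cleaning_report"
  )
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "<cleaning_report> %d raw - %d duplicates - %d staff = %d items\n",
    x$n_raw, x$n_duplicates_removed, x$n_staff_removed, x$n_final
  ))
  invisible(x)
}

#' Remove within-thread exact-text duplicates
#'
#' Accidental double submissions are identified by comparing the SHA-1
#' fingerprint of each item's text within its thread: items of a thread
#' that share a fingerprint are collapsed to the single earliest item
#' (ties broken by smallest `item_id`). Identical text in *different*
#' threads is retained — only within-thread repeats are treated as
#' duplicates.
#'
#' @param s An [interaction_set]; every item must carry `text` or a
#'   precomputed `text_hash`.
#' @return A list with elements `set` (deduplicated [interaction_set]) and
#'   `report` (a `cleaning_report`; `n_staff_removed` is 0 here).
#' @export
deduplicate <- function(s) {
  stopifnot(inherits(s, "interaction_set"))
  items <- s$items
  if (nrow(items) == 0) {
    return(list(set = s, report = new_cleaning_report(0, character(), character())))
  }
  if (anyNA(items$text_hash)) {
    stop("item(s) lacking both text and text_hash: ",
         paste(head(items$item_id[is.na(items$text_hash)], 5), collapse = ", "),
         call. = FALSE)
  }
  ord <- order(items$thread_id, items$text_hash, items$timestamp,
               items$item_id)
  key <- paste(items$thread_id[ord], items$text_hash[ord], sep = "\r")
  first_of_group <- !duplicated(key)
  keep_rows <- sort(ord[first_of_group])
  removed <- items$item_id[-keep_rows]
  if (length(removed) == 0) removed <- character()
  surv <- items[keep_rows, , drop = FALSE]
  out <- interaction_set(surv, s$period_start, s$period_end)
  list(set = out, report = new_cleaning_report(nrow(items), removed, character()))
}

#' Remove all items authored by listed accounts
#'
#' Used to drop the network's staff account (a single moderated account
#' that answers user questions) so that analyses cover user-to-user
#' interaction only. Unknown ids remove nothing.
#'
#' @param s An [interaction_set].
#' @param account_ids Character vector of user ids to exclude.
#' @return A list with `set` (filtered [interaction_set]) and `report`
#'   (a `cleaning_report`; `n_duplicates_removed` is 0 here).
#' @export
exclude_accounts <- function(s, account_ids) {
  stopifnot(inherits(s, "interaction_set"))
  account_ids <- as.character(account_ids)
  drop <- s$items$user_id %in% account_ids
  out <- interaction_set(s$items[!drop, , drop = FALSE],
                         s$period_start, s$period_end)
  list(set = out,
       report = new_cleaning_report(nrow(s$items), character(),
                                    s$items$item_id[drop]))
}

#' Full cleaning pipeline: deduplicate, then exclude staff accounts
#'
#' Composition of [deduplicate()] and [exclude_accounts()] with a combined
#' report. The report satisfies
#' `n_raw = n_final + n_duplicates_removed + n_staff_removed`, and the
#' pipeline is idempotent: running it again removes nothing.
#'
#' @param s An [interaction_set].
#' @param staff_ids Character vector of staff account ids.
#' @return A list with `set` (cleaned [interaction_set]) and `report`
#'   (combined `cleaning_report`).
#' @examples
#' sim <- simulate_network(sim_config(n_users = 30, seed = 1))
#' raw <- inject_artifacts(sim$set, sim_config(n_users = 30, seed = 2,
#'                                             duplicate_prob = 0.05,
#'                                             staff_reply_prob = 0.2))
#' res <- clean_pipeline(raw$set, staff_ids = "quitline_staff")
#' res$report
#' @export
clean_pipeline <- function(s, staff_ids = character()) {
  stopifnot(inherits(s, "interaction_set"))
  stage1 <- deduplicate(s)
  stage2 <- exclude_accounts(stage1$set, staff_ids)
  report <- new_cleaning_report(
    n_raw = nrow(s$items),
    duplicate_item_ids = stage1$report$duplicate_item_ids,
    staff_item_ids = stage2$report$staff_item_ids
  )
  list(set = stage2$set, report = report)
}
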