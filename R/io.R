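#' Read an interaction extract from CSV or JSON-lines
#'
#' Required columns/keys: `item_id`, `user_id`, `timestamp` (ISO-8601),
#' `kind` (`post`/`comment`), `thread_id`. Optional: `text`, `word_count`,
#' `text_hash`; when `text` is present, `word_count` and `text_hash` are
#' recomputed from it. Comments whose thread root is absent are loaded and
#' recorded as orphans, not discarded.
#'
#' @param path Path to the file.
#' @param format `"csv"` (comma-separated, UTF-8, header row) or `"jsonl"`
#'   (one JSON object per line).
#' @param period_start,period_end Optional analysis-period bounds; default
#'   to the observed date range.
#' @param tz Timezone used to interpret the naive timestamps (default UTC;
#'   timestamps are treated as a single local clock, no arithmetic across
#'   zones is performed).
#' @return An [interaction_set].
#' @export
read_interactions <- function(path, format = c("csv", "jsonl"),
                              period_start = NULL, period_end = NULL,
                              tz = "UTC") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    df <- jsonlite::stream_in(textConnection(lines), verbose = FALSE)
    df <- tibble::as_tibble(df)
  }
  required <- c("item_id", "user_id", "timestamp", "kind", "thread_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ts <- parse_iso_timestamp(as.character(df$timestamp), tz = tz)
  if (anyNA(ts)) {
    stop("unparseable timestamp at row(s): ",
         paste(head(which(is.na(ts)), 5), collapse = ", "), call. = FALSE)
  }
  df$timestamp <- ts
  if ("word_count" %in% names(df)) df$word_count <- as.integer(df$word_count)
  s <- interaction_set(df, period_start = period_start,
                       period_end = period_end)
  if (length(s$orphans) > 0) {
    message(length(s$orphans), " orphan comment(s) logged (thread root ",
            "not in file); ids retained in $orphans")
  }
  s
}

parse_iso_timestamp <- function(x, tz = "UTC") {
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = tz, format = "%Y-%m-%d %H:%M:%S")
  # date-only rows get midnight
  dateish <- is.na(out) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[dateish] <- as.POSIXct(x[dateish], tz = tz, format = "%Y-%m-%d")
  out
}

#' Write an interaction set to CSV or JSON-lines
#'
#' Timestamps are serialised as ISO-8601 (`YYYY-MM-DDTHH:MM:SS`) so a
#' write/read round trip reproduces the set field-for-field.
#'
#' @param s An [interaction_set].
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(s, path, format = c("csv", "jsonl")) {
  stopifnot(inherits(s, "interaction_set"))
  format <- match.arg(format)
  df <- s$items
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%S",
                         tz = attr_tz(df$timestamp))
  if (format == "csv") {
    readr::write_csv(df, path, na = "", progress = FALSE)
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    jsonlite::stream_out(as.data.frame(df), con, verbose = FALSE,
                         na = "null", auto_unbox = TRUE)
  }
  invisible(path)
}

#' Write a cleaning report as JSON
#'
#' @param report A `cleaning_report` (from [deduplicate()],
#'   [exclude_accounts()] or [clean_pipeline()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  stopifnot(inherits(report, "cleaning_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file holds any subset of the arguments of [sim_config()]; omitted
#' entries keep their defaults. `engagement_mixture` is a list of mappings
#' with keys `class`, `prop`, `items_per_day`, `active_days`, `decay_days`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `sim_config` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$engagement_mixture) && !is.data.frame(raw$engagement_mixture)) {
    raw$engagement_mixture <- dplyr::bind_rows(raw$engagement_mixture)
  }
  for (f in c("period_start", "period_end")) {
    if (!is.null(raw[[f]])) raw[[f]] <- as.Date(raw[[f]])
  }
  do.call(sim_config, raw)
}

#' Read an event-date calendar (public holidays etc.)
#'
#' Accepts a CSV with a `date` column (extra columns such as `name` are
#' kept but unused) or a YAML file holding a list of ISO dates.
#'
#' @param path Path to the calendar file. Defaults to the bundled New
#'   Zealand calendar for 2011-2012 (public holidays plus World Smokefree
#'   Day, 31 May).
#' @return A `Date` vector.
#' @export
read_holidays <- function(path = system.file("extdata", "nz_events_2011_2012.csv",
                                             package = "ocsntools")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    return(as.Date(unlist(yaml::read_yaml(path))))
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!"date" %in% names(df)) stop("calendar file needs a 'date' column",
                                   call. = FALSE)
  as.Date(df$date)
}
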