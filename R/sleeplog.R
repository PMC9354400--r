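# Sleep-log data model: CSV parsing, 5-minute epoch rasterization, validation.
#
# A logical day is anchored at 03:00 and covers decimal hours [3, 27), so the
# morning wake window (3-10 h) and the evening bed window (18-26 h) each fall
# inside a single logical day; clock times after midnight are represented on
# the extended scale (01:27 -> 25.45).

#' Read sleep intervals from CSV
#'
#' Expects columns `child_id,date,start,end,next_day`: ISO-8601 `date` of the
#' interval start, `start`/`end` as "HH:MM" clock strings, and `next_day` 1
#' when `end` falls on the following calendar day.
#'
#' @param path path to an intervals CSV (lines starting with `#` are ignored).
#' @return a data frame of class `sleep_intervals` with `child_id`, `date`
#'   (`Date`), and numeric `start`, `end` in decimal hours relative to
#'   midnight of `date` (`end` may exceed 24).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("child_id,date,start,end,next_day",
#'              "c1,2014-09-01,21:00,07:00,1"), f)
#' read_intervals(f)
read_intervals <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", colClasses = "character")
  stopifnot_cols(df, c("child_id", "date", "start", "end", "next_day"), path)
  as_sleep_intervals(data.frame(
    child_id = df$child_id,
    date = as.Date(df$date),
    start = parse_hhmm(df$start, "start time"),
    end = parse_hhmm(df$end, "end time") + 24 * as.numeric(df$next_day),
    stringsAsFactors = FALSE
  ))
}

#' Construct a validated set of sleep intervals
#'
#' @param df data frame with `child_id`, `date` (Date), `start`, `end`
#'   (decimal hours; `end` relative to `date`, may exceed 24).
#' @return the data frame with class `sleep_intervals`.
#' @export
as_sleep_intervals <- function(df) {
  stopifnot_cols(df, c("child_id", "date", "start", "end"), "intervals")
  bad_start <- df$start < 0 | df$start >= 24
  if (any(bad_start)) {
    stop(sprintf("interval row %d: start %.3f outside [0, 24)",
                 which(bad_start)[1], df$start[which(bad_start)[1]]),
         call. = FALSE)
  }
  dur <- df$end - df$start
  if (any(dur <= 0)) {
    i <- which(dur <= 0)[1]
    stop(sprintf("interval row %d: end (%.3f) <= start (%.3f) and no next-day marker",
                 i, df$end[i], df$start[i]), call. = FALSE)
  }
  if (any(dur > 24)) {
    stop(sprintf("interval row %d: duration %.2f h exceeds 24 h",
                 which(dur > 24)[1], dur[which(dur > 24)[1]]), call. = FALSE)
  }
  class(df) <- c("sleep_intervals", "data.frame")
  df
}

#' Read daily flags from CSV
#'
#' Columns `child_id,date,breakfast,self_awake,night_wakings`; the last may be
#' empty when parents did not report night-waking counts.
#'
#' @param path path to a daily-flags CSV.
#' @return data frame with `child_id`, `date` (Date), integer `breakfast`,
#'   `self_awake`, and `night_wakings` (NA when absent).
#' @export
read_daily_flags <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", colClasses = "character")
  stopifnot_cols(df, c("child_id", "date", "breakfast", "self_awake",
                       "night_wakings"), path)
  nw <- suppressWarnings(as.integer(df$night_wakings))
  data.frame(
    child_id = df$child_id,
    date = as.Date(df$date),
    breakfast = as.integer(df$breakfast),
    self_awake = as.integer(df$self_awake),
    night_wakings = nw,
    stringsAsFactors = FALSE
  )
}

#' Read child metadata from CSV
#'
#' Columns `child_id,age_months,sex,start_date` (sex may be empty; metadata
#' parsing is tolerant of partial missingness).
#'
#' @param path path to a children CSV.
#' @return data frame with `child_id`, `age_months`, `sex`, `start_date`.
#' @export
read_children <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", colClasses = "character")
  stopifnot_cols(df, c("child_id", "age_months", "sex", "start_date"), path)
  data.frame(
    child_id = df$child_id,
    age_months = as.integer(df$age_months),
    sex = ifelse(nzchar(trimws(df$sex)), df$sex, NA_character_),
    start_date = as.Date(df$start_date),
    stringsAsFactors = FALSE
  )
}

#' Build a rasterized sleep log for one child
#'
#' Rasterizes sleep intervals onto an `n_days` x 288 grid of 5-minute epochs
#' (1 = awake, 0 = asleep, NA = missing day). Logical day `d` covers decimal
#' hours [3, 27) anchored at 03:00 of `start_date + d - 1`. An epoch is asleep
#' iff its half-open 5-minute window is fully covered by a sleep interval;
#' partial coverage counts as awake. Intervals may begin the evening before
#' `start_date` or run past the final 03:00 boundary; the parts outside the
#' observation span are truncated. A calendar day with neither an interval nor
#' a flags row is marked missing (all-NA row).
#'
#' @param intervals `sleep_intervals` for this child (see [read_intervals()]).
#' @param flags daily flags data frame for this child (see
#'   [read_daily_flags()]); may have zero rows.
#' @param child_id child identifier.
#' @param age_months age in months (0-83 for screening).
#' @param start_date first calendar day of the observation (`Date`).
#' @param sex optional sex code.
#' @param n_days number of observed days (14 in the standard protocol).
#' @return an object of class `sleep_log`.
#' @export
build_sleep_log <- function(intervals, flags, child_id, age_months,
                            start_date, sex = NA_character_, n_days = 14L) {
  start_date <- as.Date(start_date)
  n_days <- as.integer(n_days)
  dates <- start_date + seq_len(n_days) - 1L

  if (nrow(intervals)) {
    intervals <- intervals[order(intervals$date, intervals$start), , drop = FALSE]
  }
  # absolute hours since 00:00 of start_date
  abs_start <- 24 * as.numeric(intervals$date - start_date) + intervals$start
  abs_end <- 24 * as.numeric(intervals$date - start_date) + intervals$end
  span <- c(DAY_START_HOUR, 24 * (n_days - 1) + DAY_END_HOUR)

  outside <- abs_end <= span[1] | abs_start >= span[2]
  if (any(outside)) {
    i <- which(outside)[1]
    stop(sprintf("interval %s %s-%s lies outside the %d-day observation span",
                 format(intervals$date[i]), format_hhmm(intervals$start[i]),
                 format_hhmm(intervals$end[i]), n_days), call. = FALSE)
  }
  if (nrow(intervals) > 1) {
    ov <- which(abs_start[-1] < abs_end[-length(abs_end)] - 1e-9)
    if (length(ov)) {
      i <- ov[1]
      stop(sprintf("overlapping sleep intervals for child %s around %s %s",
                   child_id, format(intervals$date[i + 1]),
                   format_hhmm(intervals$start[i + 1])), call. = FALSE)
    }
  }

  n_epochs <- n_days * EPOCHS_PER_DAY
  state <- rep(1L, n_epochs)  # awake unless covered
  for (i in seq_along(abs_start)) {
    s <- max(abs_start[i], span[1])
    e <- min(abs_end[i], span[2])
    if (e <= s) next
    k0 <- ceiling((s - DAY_START_HOUR) * 12 - 1e-9)       # 0-based first full epoch
    k1 <- floor((e - DAY_START_HOUR) * 12 + 1e-9) - 1     # 0-based last full epoch
    if (k1 >= k0) state[(k0 + 1):(k1 + 1)] <- 0L
  }
  grid <- matrix(state, nrow = n_days, ncol = EPOCHS_PER_DAY, byrow = TRUE)

  # align flags to the observation dates
  fl <- data.frame(date = dates, breakfast = NA_integer_,
                   self_awake = NA_integer_, night_wakings = NA_integer_)
  if (nrow(flags)) {
    idx <- match(fl$date, as.Date(flags$date))
    hit <- !is.na(idx)
    fl$breakfast[hit] <- flags$breakfast[idx[hit]]
    fl$self_awake[hit] <- flags$self_awake[idx[hit]]
    fl$night_wakings[hit] <- flags$night_wakings[idx[hit]]
  }

  recorded <- dates %in% intervals$date | !is.na(fl$breakfast) |
    !is.na(fl$self_awake) | !is.na(fl$night_wakings)
  grid[!recorded, ] <- NA_integer_

  structure(list(child_id = child_id,
                 age_months = as.integer(age_months),
                 sex = sex,
                 start_date = start_date,
                 n_days = n_days,
                 grid = grid,
                 flags = fl),
            class = "sleep_log")
}

#' @export
print.sleep_log <- function(x, ...) {
  rep <- validate_sleep_log(x)
  cat(sprintf("<sleep_log> child %s, age %d months, %d days from %s (%s)\n",
              x$child_id, x$age_months, x$n_days, format(x$start_date),
              if (rep$complete) "complete" else
                sprintf("%d missing day(s)", length(rep$missing_days))))
  invisible(x)
}

#' Validate a sleep log
#'
#' Report-only check used to exclude incomplete records from screening:
#' lists missing days and out-of-range daily flags.
#'
#' @param log a `sleep_log`.
#' @param max_missing_days a log with more missing days than this is flagged
#'   as unusable for screening (default 3).
#' @return list with `complete` (no missing days), `usable`, `missing_days`
#'   (dates), and `issues` (character).
#' @export
validate_sleep_log <- function(log, max_missing_days = 3L) {
  missing_day <- apply(is.na(log$grid), 1, all)
  dates <- log$start_date + seq_len(log$n_days) - 1L
  issues <- character(0)
  partial <- apply(is.na(log$grid), 1, any) & !missing_day
  if (any(partial)) issues <- c(issues, sprintf(
    "day %s: partially missing epochs", format(dates[partial])))
  for (col in c("breakfast", "self_awake")) {
    v <- log$flags[[col]][!missing_day]
    bad <- !is.na(v) & !(v %in% c(0L, 1L))
    if (any(bad)) issues <- c(issues, sprintf("non-binary flag '%s'", col))
  }
  nw <- log$flags$night_wakings
  if (any(!is.na(nw) & nw < 0)) issues <- c(issues, "negative night_wakings")
  if (!all(log$grid[!is.na(log$grid)] %in% c(0L, 1L)))
    issues <- c(issues, "non-binary epoch state")
  list(complete = !any(missing_day),
       usable = sum(missing_day) <= max_missing_days && length(issues) == 0L,
       missing_days = dates[missing_day],
       issues = issues)
}

#' Assemble a cohort of sleep logs from the three input tables
#'
#' @param intervals `sleep_intervals` for all children.
#' @param daily daily flags for all children.
#' @param children child metadata (see [read_children()]).
#' @param labels optional data frame `child_id,label` with binary
#'   sleep-quality labels (1 = no severe disorder, 0 = severe).
#' @param n_days days per log (default 14).
#' @return object of class `sleep_cohort`: a list with `logs` (named list of
#'   `sleep_log`) and `labels` (named integer vector or NULL).
#' @export
build_cohort <- function(intervals, daily, children, labels = NULL,
                         n_days = 14L) {
  if (anyDuplicated(children$child_id))
    stop("duplicate child_id in children table", call. = FALSE)
  logs <- lapply(seq_len(nrow(children)), function(i) {
    id <- children$child_id[i]
    build_sleep_log(
      intervals[intervals$child_id == id, , drop = FALSE],
      daily[daily$child_id == id, , drop = FALSE],
      child_id = id,
      age_months = children$age_months[i],
      start_date = children$start_date[i],
      sex = children$sex[i],
      n_days = n_days
    )
  })
  names(logs) <- children$child_id
  lab <- NULL
  if (!is.null(labels)) {
    lab <- as.integer(labels$label)[match(children$child_id, labels$child_id)]
    names(lab) <- children$child_id
  }
  structure(list(logs = logs, labels = lab), class = "sleep_cohort")
}

#' @export
print.sleep_cohort <- function(x, ...) {
  cat(sprintf("<sleep_cohort> %d children%s\n", length(x$logs),
              if (is.null(x$labels)) "" else
                sprintf(" (%d labeled severe)", sum(x$labels == 0, na.rm = TRUE))))
  invisible(x)
}
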