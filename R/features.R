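# Feature extraction: sleep-wake rate curves, sigmoid (logistic) fits of
# wake-up and bed times, and the remaining diary summary variables.

#' Average sleep-wake rate curve over a time window
#'
#' For each 5-minute epoch in the window, the mean of the awake state (0/1)
#' over all non-missing observed days: the "sleep-wake rate" curve to which
#' the sigmoid is fitted. Windows may extend past 27.0 (03:00 next day, e.g.
#' a nocturnal window ending 33.0 = 09:00); hours >= 27 are taken from the
#' following day's grid row, so such windows use days 1..n_days-1.
#'
#' @param log a `sleep_log`.
#' @param window numeric length-2, decimal hours within [3, 33).
#' @return object of class `rate_curve`: list with `times` (epoch starts),
#'   `rates` (in [0, 1]), `window`, `n_days_used`.
#' @export
average_state_curve <- function(log, window) {
  stopifnot(length(window) == 2, window[1] < window[2],
            window[1] >= DAY_START_HOUR, window[2] <= 33)
  times <- seq(window[1], window[2] - EPOCH_HOURS, by = EPOCH_HOURS)
  cols <- round((times - DAY_START_HOUR) * 12) + 1L   # may exceed 288
  wraps <- cols > EPOCHS_PER_DAY
  last_day <- if (any(wraps)) log$n_days - 1L else log$n_days
  if (last_day < 1L) stop("window extends past the final observed day", call. = FALSE)
  rows <- seq_len(last_day)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(times))
  vals[, !wraps] <- log$grid[rows, cols[!wraps], drop = FALSE]
  if (any(wraps))
    vals[, wraps] <- log$grid[rows + 1L, cols[wraps] - EPOCHS_PER_DAY, drop = FALSE]
  ok <- stats::complete.cases(vals)
  if (!any(ok)) stop("no non-missing day covers the requested window", call. = FALSE)
  structure(list(times = times,
                 rates = colMeans(vals[ok, , drop = FALSE]),
                 window = window,
                 n_days_used = sum(ok)),
            class = "rate_curve")
}

sigmoid_y <- function(p, x) p[1] + (p[2] - p[1]) / (1 + exp((p[3] - x) / p[4]))

#' Fit the sleep-wake sigmoid to a rate curve
#'
#' Fits y = a + (b - a) / (1 + exp((c - x)/d)) by bounded nonlinear least
#' squares (Levenberg-Marquardt). `c` is the time at which sleep and wake
#' states are equally likely; `d` is the slope parameter measuring day-to-day
#' variation of the transition time (near 0 for a perfectly regular schedule;
#' negative for falling, i.e. bed-time, fits). Because convergence of the
#' nonlinear fit is sensitive to initial values, the fit is repeated
#' `n_repeats` times with small i.i.d. uniform jitter added to every rate, and
#' the final estimate is the mean of the converged repeats.
#'
#' @param curve a `rate_curve`.
#' @param direction "rising" (wake-up: awake rate goes 0 to 1, d > 0) or
#'   "falling" (bed: 1 to 0, d < 0).
#' @param n_repeats number of jittered refits (default 100).
#' @param jitter_eps half-width of the uniform jitter (default 0.01).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return object of class `sigmoid_fit`: list with `a`, `b`, `c`, `d`,
#'   `n_repeats`, `converged_fraction`, `residual_rms`, `window`, `direction`.
#' @export
fit_sigmoid <- function(curve, direction = c("rising", "falling"),
                        n_repeats = 100L, jitter_eps = 0.01, seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(n_repeats >= 1)
  x <- curve$times
  y <- curve$rates
  win <- curve$window
  if (max(y) - min(y) < 1e-6) {
    stop(sprintf("cannot fit sigmoid: rate curve is constant at %.3f over (%g, %g)",
                 y[1], win[1], win[2]), call. = FALSE)
  }
  rising <- direction == "rising"
  # data-driven initial transition time: first 0.5-crossing on the grid
  cross <- if (rising) which(y >= 0.5) else which(y <= 0.5)
  c0 <- if (length(cross)) x[cross[1]] else mean(win)
  p0 <- c(a = if (rising) 0 else 0, b = 1, c = c0,
          d = if (rising) 0.25 else -0.25)
  lower <- c(-0.2, -0.2, win[1], if (rising) 1e-4 else -2)
  upper <- c(1.2, 1.2, win[2], if (rising) 2 else -1e-4)

  with_seed(seed, {
    fits <- matrix(NA_real_, nrow = n_repeats, ncol = 4)
    for (r in seq_len(n_repeats)) {
      yj <- if (jitter_eps > 0) y + stats::runif(length(y), -jitter_eps, jitter_eps) else y
      res <- tryCatch(
        minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                           fn = function(p, x, y) sigmoid_y(p, x) - y,
                           x = x, y = yj,
                           control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(res) && res$info %in% 1:4 && all(is.finite(res$par)))
        fits[r, ] <- res$par
    }
    conv <- stats::complete.cases(fits)
    frac <- mean(conv)
    if (frac < 0.5) {
      stop(sprintf("sigmoid fit failed: only %.0f%% of %d repeats converged (%s window %g-%g)",
                   100 * frac, n_repeats, direction, win[1], win[2]),
           call. = FALSE)
    }
    p <- colMeans(fits[conv, , drop = FALSE])
    structure(list(a = p[1], b = p[2], c = p[3], d = p[4],
                   n_repeats = n_repeats,
                   converged_fraction = frac,
                   residual_rms = sqrt(mean((sigmoid_y(p, x) - y)^2)),
                   window = win, direction = direction),
              class = "sigmoid_fit")
  })
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("<sigmoid_fit> %s (%g, %g): c = %.3f h, d = %.4f h (a = %.3f, b = %.3f; %d%% converged, rms %.4f)\n",
              x$direction, x$window[1], x$window[2], x$c, x$d, x$a, x$b,
              round(100 * x$converged_fraction), x$residual_rms))
  invisible(x)
}

#' Wake-up time and its variation
#'
#' Rising sigmoid fit of the 3:00-10:00 sleep-wake rate curve: returns the
#' transition time `c` (wake-up time, decimal hours) and slope `d` (wake-up
#' time variation, hours; approaches 0 when wake time is constant).
#'
#' @inheritParams fit_sigmoid
#' @param log a `sleep_log`.
#' @return named numeric: `wake_up_time`, `wake_up_time_variation`.
#' @export
wake_time_features <- function(log, n_repeats = 100L, jitter_eps = 0.01,
                               seed = NULL) {
  fit <- fit_sigmoid(average_state_curve(log, c(3, 10)), "rising",
                     n_repeats, jitter_eps, seed)
  c(wake_up_time = unname(fit$c), wake_up_time_variation = unname(fit$d))
}

#' Bed time and its variation
#'
#' Falling sigmoid fit of the 18:00-02:00 sleep-wake rate curve on the
#' extended 24-hour scale (01:27 -> 25.45). The slope `d` is negative by the
#' sign convention of the falling fit.
#'
#' @inheritParams wake_time_features
#' @return named numeric: `bed_time`, `bed_time_variation` (negative).
#' @export
bed_time_features <- function(log, n_repeats = 100L, jitter_eps = 0.01,
                              seed = NULL) {
  fit <- fit_sigmoid(average_state_curve(log, c(18, 26)), "falling",
                     n_repeats, jitter_eps, seed)
  c(bed_time = unname(fit$c), bed_time_variation = unname(fit$d))
}

non_missing_days <- function(log) which(!apply(is.na(log$grid), 1, all))

#' Total sleep duration (hours per 24-h day)
#'
#' Mean over non-missing days of the time asleep within each logical day
#' [3, 27).
#' @param log a `sleep_log`.
#' @return hours in [0, 24].
#' @export
total_sleep_duration <- function(log) {
  days <- non_missing_days(log)
  if (!length(days)) stop("all days missing", call. = FALSE)
  mean(rowSums(log$grid[days, , drop = FALSE] == 0L) * EPOCH_HOURS)
}

nocturnal_cols_evening <- function() ((19 - DAY_START_HOUR) * 12 + 1):EPOCHS_PER_DAY
nocturnal_cols_morning <- function() 1:((9 - DAY_START_HOUR) * 12)

# awake-state vector over one nocturnal window [19, 33): evening of day d
# plus morning of day d + 1; NULL if either day is missing
nocturnal_states <- function(log, d) {
  v <- c(log$grid[d, nocturnal_cols_evening()],
         log$grid[d + 1L, nocturnal_cols_morning()])
  if (anyNA(v)) NULL else v
}

#' Nocturnal sleep duration (hours per night)
#'
#' Mean time asleep between 19:00 and 09:00 the next morning, averaged over
#' the complete nocturnal windows (nights 1..n_days-1 of the log; the final
#' night is incomplete because recording stops at 03:00 after day n_days).
#' @param log a `sleep_log`.
#' @return hours in [0, 14].
#' @export
nocturnal_sleep_duration <- function(log) {
  vals <- numeric(0)
  for (d in seq_len(log$n_days - 1L)) {
    v <- nocturnal_states(log, d)
    if (!is.null(v)) vals <- c(vals, sum(v == 0L) * EPOCH_HOURS)
  }
  if (!length(vals)) stop("no complete nocturnal window", call. = FALSE)
  mean(vals)
}

# number of maximal awake runs strictly inside the nocturnal sleep period
count_wakings <- function(v) {
  asleep <- which(v == 0L)
  if (!length(asleep)) return(0L)
  inner <- v[asleep[1]:asleep[length(asleep)]]
  r <- rle(inner)
  sum(r$values == 1L)
}

#' Mean number of night wakings
#'
#' If parents reported night-waking counts for at least half of the
#' non-missing days, the mean of the reported counts is used. Otherwise
#' wakings are counted from the epoch grid: maximal awake runs strictly
#' between sleep onset (first asleep epoch after 19:00) and final awakening
#' (last asleep epoch before 09:00), averaged over complete nights.
#' @param log a `sleep_log`.
#' @return mean count per night (>= 0).
#' @export
night_wakings <- function(log) {
  days <- non_missing_days(log)
  rep_counts <- log$flags$night_wakings[days]
  if (sum(!is.na(rep_counts)) >= length(days) / 2)
    return(mean(rep_counts, na.rm = TRUE))
  vals <- integer(0)
  for (d in seq_len(log$n_days - 1L)) {
    v <- nocturnal_states(log, d)
    if (!is.null(v)) vals <- c(vals, count_wakings(v))
  }
  if (!length(vals)) stop("no complete nocturnal window", call. = FALSE)
  mean(vals)
}

#' Mean number of evening naps
#'
#' Mean over non-missing days of the number of maximal asleep runs that
#' intersect the 15:00-19:00 window. An episode count (not a rate): values
#' above 1 indicate multiple evening sleep episodes per day.
#' @param log a `sleep_log`.
#' @return mean episode count per day.
#' @export
evening_nap <- function(log) {
  win_cols <- ((15 - DAY_START_HOUR) * 12 + 1):((19 - DAY_START_HOUR) * 12)
  days <- non_missing_days(log)
  if (!length(days)) stop("all days missing", call. = FALSE)
  counts <- vapply(days, function(d) {
    v <- log$grid[d, ]
    r <- rle(v == 0L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sum(r$values & starts <= max(win_cols) & ends >= min(win_cols))
  }, numeric(1))
  mean(counts)
}

#' Breakfast rate
#'
#' Fraction of non-missing days on which the child ate breakfast.
#' @param log a `sleep_log`.
#' @return fraction in [0, 1].
#' @export
breakfast_rate <- function(log) {
  days <- non_missing_days(log)
  mean(log$flags$breakfast[days], na.rm = TRUE)
}

#' Self-awakening rate
#'
#' Fraction of non-missing days on which the child woke up by themselves.
#' @param log a `sleep_log`.
#' @return fraction in [0, 1].
#' @export
self_awake_rate <- function(log) {
  days <- non_missing_days(log)
  mean(log$flags$self_awake[days], na.rm = TRUE)
}

#' Names of the ten sleep-log features
#' @return character vector of the canonical feature names.
#' @export
feature_names <- function() {
  c("wake_up_time", "wake_up_time_variation", "bed_time",
    "bed_time_variation", "total_sleep_duration", "nocturnal_sleep_duration",
    "night_wakings", "evening_nap", "breakfast", "self_awake")
}

#' Extract the ten screening features from a sleep log
#'
#' Assembles the full feature vector: sigmoid-fitted wake-up and bed times
#' with their variation parameters, total and nocturnal sleep durations,
#' night wakings, evening naps, and breakfast/self-awakening rates.
#' Deterministic given `seed`.
#'
#' @inheritParams wake_time_features
#' @return one-row data frame with `child_id`, `age_months`, and the ten
#'   features named as in [feature_names()].
#' @export
#' @examples
#' coh <- simulate_cohort(simulation_config(group_sizes = c("5" = 1), seed = 1))
#' extract_features(build_cohort(coh$intervals, coh$daily, coh$children)$logs[[1]],
#'                  n_repeats = 10, seed = 1)
extract_features <- function(log, n_repeats = 100L, jitter_eps = 0.01,
                             seed = NULL) {
  grab <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("feature '%s' failed for child %s: %s",
                   what, log$child_id, conditionMessage(e)), call. = FALSE)
    })
  }
  seeds <- if (is.null(seed)) list(NULL, NULL) else
    list(derive_seed(seed, 1L), derive_seed(seed, 2L))
  wf <- grab("wake_up_time", wake_time_features(log, n_repeats, jitter_eps, seeds[[1]]))
  bf <- grab("bed_time", bed_time_features(log, n_repeats, jitter_eps, seeds[[2]]))
  out <- data.frame(
    child_id = log$child_id,
    age_months = log$age_months,
    wake_up_time = wf[["wake_up_time"]],
    wake_up_time_variation = wf[["wake_up_time_variation"]],
    bed_time = bf[["bed_time"]],
    bed_time_variation = bf[["bed_time_variation"]],
    total_sleep_duration = grab("total_sleep_duration", total_sleep_duration(log)),
    nocturnal_sleep_duration = grab("nocturnal_sleep_duration",
                                    nocturnal_sleep_duration(log)),
    night_wakings = grab("night_wakings", night_wakings(log)),
    evening_nap = grab("evening_nap", evening_nap(log)),
    breakfast = grab("breakfast", breakfast_rate(log)),
    self_awake = grab("self_awake", self_awake_rate(log)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Extract features for every child in a cohort
#'
#' Per-child failures are collected rather than aborting the run; a master
#' seed fans out to per-child seeds by a counter scheme, so results do not
#' depend on cohort ordering.
#'
#' @param cohort a `sleep_cohort`.
#' @inheritParams extract_features
#' @param max_missing_days children with more missing days are skipped and
#'   reported (default 3).
#' @return list with `features` (data frame, one row per successful child)
#'   and `failures` (data frame `child_id,reason`).
#' @export
extract_cohort_features <- function(cohort, n_repeats = 100L,
                                    jitter_eps = 0.01, seed = NULL,
                                    max_missing_days = 3L) {
  rows <- list()
  fails <- list()
  for (i in seq_along(cohort$logs)) {
    log <- cohort$logs[[i]]
    vrep <- validate_sleep_log(log, max_missing_days)
    if (!vrep$usable) {
      fails[[length(fails) + 1L]] <- data.frame(
        child_id = log$child_id,
        reason = paste(c(sprintf("%d missing day(s)", length(vrep$missing_days))[
          length(vrep$missing_days) > 0], vrep$issues), collapse = "; "),
        stringsAsFactors = FALSE)
      next
    }
    child_seed <- if (is.null(seed)) NULL else
      derive_seed(seed, string_counter(log$child_id))
    row <- tryCatch(extract_features(log, n_repeats, jitter_eps, child_seed),
                    error = function(e) e)
    if (inherits(row, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        child_id = log$child_id, reason = conditionMessage(row),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- row
    }
  }
  list(features = if (length(rows)) do.call(rbind, rows) else NULL,
       failures = if (length(fails)) do.call(rbind, fails) else
         data.frame(child_id = character(0), reason = character(0)))
}
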