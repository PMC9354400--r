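# Fixtures are built in code: hand-crafted sleep schedules and rate curves.

START_DATE <- as.Date("2014-09-01")

# intervals for a nightly schedule: bed_times / wake_times are recycled over
# nights -1 .. n_days-1 (the lead-in night covers day 1's morning).
schedule_intervals <- function(child_id = "c1", bed_times = 21, wake_times = 7,
                               n_days = 14, extra = NULL) {
  nights <- (-1):(n_days - 1)
  beds <- rep_len(bed_times, length(nights))
  wakes <- rep_len(wake_times, length(nights))
  late <- beds >= 24  # bed after midnight: interval starts on the next date
  df <- data.frame(child_id = child_id,
                   date = START_DATE + nights + late,
                   start = ifelse(late, beds - 24, beds),
                   end = ifelse(late, wakes, wakes + 24),
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- rbind(df, extra)
  as_sleep_intervals(df)
}

# extra daytime intervals on every day (or a subset): start/end in decimal h
daily_extra <- function(child_id = "c1", start, end, days = 0:13) {
  do.call(rbind, lapply(days, function(o) {
    data.frame(child_id = child_id, date = START_DATE + o,
               start = start, end = end, stringsAsFactors = FALSE)
  }))
}

flags_df <- function(child_id = "c1", n_days = 14, breakfast = 1,
                     self_awake = 1, night_wakings = NA_integer_) {
  data.frame(child_id = child_id,
             date = START_DATE + 0:(n_days - 1),
             breakfast = rep_len(breakfast, n_days),
             self_awake = rep_len(self_awake, n_days),
             night_wakings = rep_len(night_wakings, n_days),
             stringsAsFactors = FALSE)
}

regular_log <- function(bed_times = 21, wake_times = 7, extra = NULL,
                        n_days = 14, flags = flags_df(n_days = n_days),
                        age_months = 30) {
  build_sleep_log(schedule_intervals("c1", bed_times, wake_times, n_days, extra),
                  flags, "c1", age_months, START_DATE, n_days = n_days)
}

# rate curve object straight from values (for sigmoid-fit unit tests)
mk_curve <- function(rates, window = c(3, 10)) {
  structure(list(times = seq(window[1], window[2] - 1 / 12, by = 1 / 12),
                 rates = rates, window = window, n_days_used = 14),
            class = "rate_curve")
}

logistic_curve <- function(a, b, cc, d, window = c(3, 10)) {
  x <- seq(window[1], window[2] - 1 / 12, by = 1 / 12)
  mk_curve(a + (b - a) / (1 + exp((cc - x) / d)), window)
}

# empirical awake-rate curve for normally distributed wake times
normal_wake_curve <- function(mu, sigma, n_days, window = c(3, 10)) {
  wt <- rnorm(n_days, mu, sigma)
  x <- seq(window[1], window[2] - 1 / 12, by = 1 / 12)
  mk_curve(vapply(x, function(t) mean(wt <= t + 1 / 24), numeric(1)), window)
}

group1_boundary <- (492.019 - 391.015) / (41.685 - 37.154)

# brute-force Wilks' lambda via base-R model fits (independent of the package)
wilks_oracle <- function(m, lb) {
  if (ncol(m) == 1) {
    a <- stats::anova(stats::lm(m[, 1] ~ factor(lb)))
    a["Residuals", "Sum Sq"] / sum(a[, "Sum Sq"])
  } else {
    summary(stats::manova(m ~ factor(lb)), test = "Wilks")$stats[1, "Wilks"]
  }
}
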