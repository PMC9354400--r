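# Synthetic labeled cohorts of 14-day sleep logs. The generator encodes
# severity at the generative-parameter level (severe profiles violate at
# least one clinical criterion: sleep onset after 22:30, more than three
# night wakings, short sleep, or schedule variation above 60 min), so labels
# are noiseless class indicators unless label noise is requested.

#' Construct a generative profile for one age group and class
#'
#' Day-level schedule draws are normal with the stated day-to-day SDs;
#' between-child heterogeneity (personal mean offsets, per-child day-to-day
#' SD spread, gamma night-waking rates, beta flag probabilities) is optional
#' and defaults to none, which is convenient for controlled experiments.
#'
#' @param group_id age group 0-8.
#' @param class 1 = non-severe, 0 = severe.
#' @param wake_mean,wake_sd mean wake-up time (decimal hours in (3, 10)) and
#'   day-to-day SD (hours).
#' @param bed_mean,bed_sd mean sleep-onset time (extended scale, in (18, 26))
#'   and day-to-day SD.
#' @param wake_between_sd,bed_between_sd SD of per-child personal means.
#' @param day_sd_spread SD of the per-child day-to-day SD around
#'   `wake_sd`/`bed_sd` (truncated at 0.02 h).
#' @param night_rate expected night wakings per night (Poisson).
#' @param night_rate_shape gamma shape for between-child rate heterogeneity
#'   (0 = homogeneous).
#' @param waking_minutes duration of each night waking.
#' @param evening_nap_prob,evening_nap_minutes daily probability and duration
#'   of a nap starting in 15:00-17:00.
#' @param afternoon_nap_prob,afternoon_nap_minutes daily probability and
#'   duration of a nap starting in 12:30-14:00.
#' @param breakfast_prob,self_awake_prob daily flag probabilities.
#' @param flag_concentration beta concentration for between-child flag
#'   probability heterogeneity (0 = homogeneous).
#' @param nap_prob_concentration beta concentration for between-child
#'   evening-nap probability heterogeneity (0 = homogeneous).
#' @return one-row data frame of class `group_profile`.
#' @export
group_profile <- function(group_id, class,
                          wake_mean, wake_sd, bed_mean, bed_sd,
                          wake_between_sd = 0, bed_between_sd = 0,
                          day_sd_spread = 0,
                          night_rate = 0, night_rate_shape = 0,
                          waking_minutes = 10,
                          evening_nap_prob = 0, evening_nap_minutes = 30,
                          afternoon_nap_prob = 0, afternoon_nap_minutes = 80,
                          breakfast_prob = 1, self_awake_prob = 1,
                          flag_concentration = 0,
                          nap_prob_concentration = 0) {
  stopifnot(group_id %in% 0:8, class %in% c(0, 1),
            wake_mean > 3, wake_mean < 10, bed_mean > 18, bed_mean < 26,
            wake_sd >= 0, bed_sd >= 0, night_rate >= 0,
            evening_nap_prob >= 0, evening_nap_prob <= 1,
            breakfast_prob >= 0, breakfast_prob <= 1,
            self_awake_prob >= 0, self_awake_prob <= 1)
  structure(data.frame(group_id = as.integer(group_id),
                       class = as.integer(class),
                       wake_mean = wake_mean, wake_sd = wake_sd,
                       bed_mean = bed_mean, bed_sd = bed_sd,
                       wake_between_sd = wake_between_sd,
                       bed_between_sd = bed_between_sd,
                       day_sd_spread = day_sd_spread,
                       night_rate = night_rate,
                       night_rate_shape = night_rate_shape,
                       waking_minutes = waking_minutes,
                       evening_nap_prob = evening_nap_prob,
                       evening_nap_minutes = evening_nap_minutes,
                       afternoon_nap_prob = afternoon_nap_prob,
                       afternoon_nap_minutes = afternoon_nap_minutes,
                       breakfast_prob = breakfast_prob,
                       self_awake_prob = self_awake_prob,
                       flag_concentration = flag_concentration,
                       nap_prob_concentration = nap_prob_concentration,
                       stringsAsFactors = FALSE),
            class = c("group_profile", "data.frame"))
}

#' Default generative profiles for all age groups
#'
#' Non-severe profiles are centered on the published cohort-level descriptive
#' statistics (wake-up time mean 6.84 h, bed time mean 21.44 h for the
#' dominant 19-47-month group) with age trends following the developmental
#' narrative: younger children wake and go to bed earlier, nap more, wake
#' more at night, and have more variable schedules. Between-child
#' heterogeneity is calibrated so cohort-level feature SDs have the published
#' orders of magnitude. Severe profiles violate the clinical criteria: mean
#' sleep onset 23:00 (after the 22:30 threshold), day-to-day schedule SD
#' 1.1 h (variation above 60 min), and an elevated night-waking rate
#' (above 3/night).
#'
#' @return data frame of `group_profile` rows, two per group (class 1 and 0).
#' @export
default_profiles <- function() {
  base <- data.frame(
    group_id = 0:8,
    wake_mean = c(6.60, 6.60, 6.65, 6.70, 6.75, 6.84, 6.90, 6.95, 7.00),
    wake_sd = c(0.55, 0.50, 0.48, 0.46, 0.46, 0.45, 0.30, 0.26, 0.25),
    bed_mean = c(20.70, 20.90, 21.00, 21.10, 21.20, 21.44, 21.55, 21.60, 21.65),
    bed_sd = c(0.60, 0.55, 0.52, 0.50, 0.48, 0.47, 0.30, 0.28, 0.27),
    night_rate = c(2.00, 1.50, 1.00, 0.60, 0.35, 0.12, 0.05, 0.04, 0.03),
    evening_nap_prob = c(0.60, 0.50, 0.35, 0.25, 0.18, 0.10, 0.04, 0.03, 0.02),
    afternoon_nap_prob = c(0.90, 0.90, 0.90, 0.90, 0.90, 0.70, 0.20, 0.10, 0.05),
    breakfast_prob = c(0.60, 0.70, 0.85, 0.93, 0.94, 0.95, 0.96, 0.97, 0.97),
    self_awake_prob = c(0.90, 0.85, 0.80, 0.80, 0.78, 0.70, 0.62, 0.58, 0.55)
  )
  rows <- lapply(0:8, function(g) {
    b <- base[base$group_id == g, ]
    ns <- group_profile(
      g, 1L, wake_mean = b$wake_mean, wake_sd = b$wake_sd,
      bed_mean = b$bed_mean, bed_sd = b$bed_sd,
      wake_between_sd = 0.45, bed_between_sd = 0.55, day_sd_spread = 0.22,
      night_rate = b$night_rate, night_rate_shape = 0.2,
      waking_minutes = 10,
      evening_nap_prob = b$evening_nap_prob,
      afternoon_nap_prob = b$afternoon_nap_prob,
      breakfast_prob = b$breakfast_prob,
      self_awake_prob = b$self_awake_prob,
      flag_concentration = 1.5, nap_prob_concentration = 4)
    sv <- group_profile(
      g, 0L, wake_mean = b$wake_mean + 0.4, wake_sd = 1.10,
      bed_mean = 23.0, bed_sd = 1.10,
      wake_between_sd = 0.45, bed_between_sd = 0.55, day_sd_spread = 0.25,
      night_rate = b$night_rate + 3.2, night_rate_shape = 0.5,
      waking_minutes = 20,
      evening_nap_prob = min(1, b$evening_nap_prob + 0.15),
      afternoon_nap_prob = b$afternoon_nap_prob,
      breakfast_prob = max(0.05, b$breakfast_prob - 0.25),
      self_awake_prob = max(0.05, b$self_awake_prob - 0.25),
      flag_concentration = 1.5, nap_prob_concentration = 4)
    rbind(ns, sv)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_profile", "data.frame")
  out
}

rbeta_mean <- function(n, mean, concentration) {
  if (concentration <= 0) return(rep(mean, n))
  mean <- min(max(mean, 1e-3), 1 - 1e-3)
  stats::rbeta(n, mean * concentration, (1 - mean) * concentration)
}

clip_count <- new.env()

#' Simulate one child's 14-day sleep log records
#'
#' Draws a nightly schedule (sleep onset and wake time, normal day-to-day
#' variation clipped to the bed window (18, 26) and wake window (3, 10)),
#' inserts Poisson-count night wakings of the stated duration at uniform
#' positions within the night, adds evening/afternoon naps with the stated
#' probabilities, and draws Bernoulli daily flags. The night before the first
#' observation day is also generated so day-1 mornings are covered. Reported
#' night-waking counts equal the realized counts of the night starting that
#' evening. Deterministic given `seed`.
#'
#' @param profile one `group_profile` row.
#' @param child_id identifier.
#' @param start_date first observation day (`Date`).
#' @param seed integer seed (optional).
#' @param n_days observation length (default 14).
#' @param age_months age to record; default midpoint of the group range.
#' @return list with `intervals` (`sleep_intervals`), `daily`, `child`
#'   (one-row metadata), `label`, and `n_clipped` (schedule draws clipped at
#'   window edges).
#' @export
simulate_child <- function(profile, child_id, start_date = as.Date("2014-09-01"),
                           seed = NULL, n_days = 14L, age_months = NULL) {
  p <- as.list(profile)
  tab <- age_group_table()[profile$group_id + 1L, ]
  if (is.null(age_months))
    age_months <- as.integer(round((tab$min_months + tab$max_months) / 2))
  if (p$wake_mean + 24 <= p$bed_mean)
    stop("degenerate profile: wake time does not follow bed time", call. = FALSE)
  start_date <- as.Date(start_date)
  n_days <- as.integer(n_days)

  with_seed(seed, {
    # child-level heterogeneity
    wake_mu <- stats::rnorm(1, p$wake_mean, p$wake_between_sd)
    bed_mu <- stats::rnorm(1, p$bed_mean, p$bed_between_sd)
    wake_mu <- min(max(wake_mu, 4), 9.5)
    bed_mu <- min(max(bed_mu, 18.5), 25.5)
    wake_sd <- if (p$day_sd_spread > 0)
      max(0.02, stats::rnorm(1, p$wake_sd, p$day_sd_spread)) else p$wake_sd
    bed_sd <- if (p$day_sd_spread > 0)
      max(0.02, stats::rnorm(1, p$bed_sd, p$day_sd_spread)) else p$bed_sd
    rate <- if (p$night_rate_shape > 0 && p$night_rate > 0)
      stats::rgamma(1, shape = p$night_rate_shape,
                    scale = p$night_rate / p$night_rate_shape)
    else p$night_rate
    pb <- rbeta_mean(1, p$breakfast_prob, p$flag_concentration)
    ps <- rbeta_mean(1, p$self_awake_prob, p$flag_concentration)
    pe <- rbeta_mean(1, p$evening_nap_prob, p$nap_prob_concentration)

    # nights i = -1 .. n_days - 1 (bed on day i evening, wake next morning)
    nights <- (-1):(n_days - 1L)
    beds <- stats::rnorm(length(nights), bed_mu, bed_sd)
    wakes <- stats::rnorm(length(nights), wake_mu, wake_sd)
    n_clip <- sum(beds < 18 | beds > 26) + sum(wakes < 3 | wakes > 10)
    beds <- pmin(pmax(beds, 18), 26)
    wakes <- pmin(pmax(wakes, 3), 10)
    wake_dur <- p$waking_minutes / 60

    seg_start <- numeric(0)  # absolute hours since 00:00 of start_date
    seg_end <- numeric(0)
    reported <- integer(length(nights))
    for (k in seq_along(nights)) {
      i <- nights[k]
      S <- 24 * i + beds[k]
      E <- 24 * (i + 1) + wakes[k]
      m <- if (rate > 0) stats::rpois(1, rate) else 0L
      cuts <- numeric(0)
      if (m > 0) {
        lo <- S + 0.75
        hi <- E - 0.75 - wake_dur
        if (hi > lo) {
          t0 <- sort(stats::runif(m, lo, hi))
          last <- -Inf
          for (tt in t0) {
            if (tt - last >= wake_dur + 0.25) {
              cuts <- c(cuts, tt)
              last <- tt
            }
          }
        }
      }
      reported[k] <- length(cuts)
      bounds <- c(S, as.vector(rbind(cuts, cuts + wake_dur)), E)
      seg_start <- c(seg_start, bounds[seq(1, length(bounds) - 1, by = 2)])
      seg_end <- c(seg_end, bounds[seq(2, length(bounds), by = 2)])
    }

    # naps on observation days 0 .. n_days - 1 (afternoon first; the evening
    # nap starts after it and ends before that evening's bed time)
    for (o in 0:(n_days - 1L)) {
      bed_today <- beds[match(o, nights)]
      aft_end <- -Inf
      if (stats::runif(1) < p$afternoon_nap_prob) {
        st <- stats::runif(1, 12.5, 14)
        aft_end <- st + p$afternoon_nap_minutes / 60 * stats::runif(1, 0.7, 1.3)
        seg_start <- c(seg_start, 24 * o + st)
        seg_end <- c(seg_end, 24 * o + aft_end)
      }
      if (stats::runif(1) < pe && aft_end + 0.25 < 17) {
        st <- stats::runif(1, max(15, aft_end + 0.25), 17)
        en <- min(st + p$evening_nap_minutes / 60 * stats::runif(1, 0.7, 1.3),
                  bed_today - 0.25)
        if (en > st + 1 / 12) {
          seg_start <- c(seg_start, 24 * o + st)
          seg_end <- c(seg_end, 24 * o + en)
        }
      }
    }

    # encode segments as dated intervals at 1-minute resolution; drop pieces
    # wholly outside the observation span [03:00 day 1, 03:00 after day n]
    seg_start <- round(seg_start * 60) / 60
    seg_end <- round(seg_end * 60) / 60
    span <- c(3, 24 * (n_days - 1) + 27)
    ok <- seg_end > seg_start & seg_end > span[1] & seg_start < span[2]
    seg_start <- seg_start[ok]
    seg_end <- seg_end[ok]
    off <- floor(seg_start / 24)
    intervals <- as_sleep_intervals(data.frame(
      child_id = child_id,
      date = start_date + off,
      start = seg_start - 24 * off,
      end = seg_end - 24 * off,
      stringsAsFactors = FALSE))

    daily <- data.frame(
      child_id = child_id,
      date = start_date + 0:(n_days - 1L),
      breakfast = as.integer(stats::runif(n_days) < pb),
      self_awake = as.integer(stats::runif(n_days) < ps),
      night_wakings = reported[match(0:(n_days - 1L), nights)],
      stringsAsFactors = FALSE)

    list(intervals = intervals,
         daily = daily,
         child = data.frame(child_id = child_id, age_months = age_months,
                            sex = NA_character_, start_date = start_date,
                            stringsAsFactors = FALSE),
         label = as.integer(p$class),
         n_clipped = n_clip)
  })
}

#' Simulation configuration
#'
#' @param group_sizes named object keyed by group id ("0".."8"): either a
#'   single count (non-severe children only) or a length-2 vector
#'   `c(nonsevere, severe)`.
#' @param seed master seed; per-child seeds are derived by a counter scheme.
#' @param n_days days per log (default 14).
#' @param start_date first observation day.
#' @param label_noise probability of flipping each child's label (default 0).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(group_sizes, seed = 1L, n_days = 14L,
                              start_date = as.Date("2014-09-01"),
                              label_noise = 0) {
  group_sizes <- as.list(group_sizes)
  stopifnot(length(group_sizes) > 0, !is.null(names(group_sizes)),
            all(names(group_sizes) %in% as.character(0:8)),
            label_noise >= 0, label_noise <= 1)
  structure(list(group_sizes = group_sizes, seed = as.integer(seed),
                 n_days = as.integer(n_days),
                 start_date = as.Date(start_date),
                 label_noise = label_noise),
            class = "simulation_config")
}

#' Simulate a labeled cohort
#'
#' Generates the three input tables (intervals, daily flags, children) plus
#' labels for the requested per-group, per-class sample sizes, reproducibly
#' from the config seed. The summary compares realized raw schedule means
#' (from the generated intervals) with the profile targets.
#'
#' @param config a [simulation_config()].
#' @param profiles profile table (default [default_profiles()]).
#' @return list with `intervals`, `daily`, `children`, `labels` (data
#'   frames), `summary`, and `n_clipped`.
#' @export
#' @examples
#' sim <- simulate_cohort(simulation_config(list("5" = c(3, 2)), seed = 7))
#' table(sim$labels$label)
simulate_cohort <- function(config, profiles = default_profiles()) {
  stopifnot(inherits(config, "simulation_config"))
  parts <- list()
  counter <- 0L
  for (gname in names(config$group_sizes)) {
    g <- as.integer(gname)
    sizes <- config$group_sizes[[gname]]
    n_ns <- as.integer(sizes[1])
    n_sv <- if (length(sizes) > 1) as.integer(sizes[2]) else 0L
    tab <- age_group_table()[g + 1L, ]
    for (cls in c(1L, 0L)) {
      n <- if (cls == 1L) n_ns else n_sv
      if (n <= 0) next
      prof <- profiles[profiles$group_id == g & profiles$class == cls, ]
      if (nrow(prof) != 1)
        stop(sprintf("no unique profile for group %d class %d", g, cls),
             call. = FALSE)
      for (j in seq_len(n)) {
        counter <- counter + 1L
        id <- sprintf("g%d_%s_%04d", g, if (cls == 1L) "ns" else "sv", j)
        age <- with_seed(derive_seed(config$seed, counter * 2L), {
          as.integer(sample(tab$min_months:tab$max_months, 1))
        })
        parts[[counter]] <- simulate_child(
          prof, id, config$start_date,
          seed = derive_seed(config$seed, counter * 2L + 1L),
          n_days = config$n_days, age_months = age)
      }
    }
  }
  if (!length(parts)) stop("empty configuration", call. = FALSE)
  intervals <- as_sleep_intervals(do.call(rbind, lapply(parts, `[[`, "intervals")))
  daily <- do.call(rbind, lapply(parts, `[[`, "daily"))
  children <- do.call(rbind, lapply(parts, `[[`, "child"))
  labels <- data.frame(child_id = children$child_id,
                       label = vapply(parts, `[[`, integer(1), "label"),
                       stringsAsFactors = FALSE)
  if (config$label_noise > 0) {
    flip <- with_seed(derive_seed(config$seed, 0L),
                      stats::runif(nrow(labels)) < config$label_noise)
    labels$label[flip] <- 1L - labels$label[flip]
  }
  one_class <- length(unique(labels$label)) < 2L

  # realized raw schedule summary: per child-night sleep onset = earliest
  # interval start in the bed window (18, 26) that night (later starts are
  # resumptions after a night waking), wake = latest morning interval end
  ext_start <- ifelse(intervals$start < 12, intervals$start + 24, intervals$start)
  night <- intervals$start >= 18 | intervals$start < 2
  key <- paste(intervals$child_id, intervals$date - (intervals$start < 2))
  onset <- tapply(ext_start[night], key[night], min)
  wake_end <- intervals$end - 24 * (intervals$end >= 24)
  morning <- wake_end > 3 & wake_end <= 10 &
    (intervals$end >= 24 | intervals$start < 10)
  mkey <- paste(intervals$child_id, intervals$date + (intervals$end >= 24))
  night_wake <- tapply(wake_end[morning], mkey[morning], max)
  ids <- sub(" .*$", "", names(onset))
  wids <- sub(" .*$", "", names(night_wake))
  per_child <- data.frame(
    child_id = sort(unique(children$child_id)))
  per_child$mean_sleep_onset <-
    as.numeric(tapply(onset, ids, mean)[per_child$child_id])
  per_child$mean_wake <-
    as.numeric(tapply(night_wake, wids, mean)[per_child$child_id])
  grp <- assign_age_group(children$age_months[match(per_child$child_id,
                                                    children$child_id)])
  cls <- labels$label[match(per_child$child_id, labels$child_id)]
  summary <- stats::aggregate(per_child[, c("mean_sleep_onset", "mean_wake")],
                              by = list(group_id = grp, class = cls),
                              FUN = mean)

  list(intervals = intervals, daily = daily, children = children,
       labels = labels, summary = summary,
       single_class = one_class,
       n_clipped = sum(vapply(parts, `[[`, numeric(1), "n_clipped")))
}
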