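# End-to-end runs: simulate, features, screen, train. Every output file
# starts with header comments recording the tool version, seed, and input
# digests; results go to files, progress messages to standard error.

output_header <- function(seed, inputs = character(0)) {
  ver <- as.character(utils::packageVersion("somnoscreen"))
  dig <- if (length(inputs)) {
    md5 <- tools::md5sum(inputs[file.exists(inputs)])
    sprintf("input %s md5=%s", basename(names(md5)), unname(md5))
  } else character(0)
  c(sprintf("somnoscreen %s", ver),
    sprintf("seed=%s", if (is.null(seed)) "none" else seed),
    dig)
}

write_output_csv <- function(df, path, seed, inputs = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", output_header(seed, inputs)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

msg <- function(...) message(sprintf(...))

#' Run: simulate a synthetic cohort to CSV files
#'
#' Writes `<out_prefix>intervals.csv`, `daily.csv`, `children.csv`,
#' `labels.csv` in the schemas consumed by [run_features()] and
#' [run_screen()].
#'
#' @param config a [simulation_config()].
#' @param out_prefix path prefix for the four output files.
#' @param profiles profile table (default [default_profiles()]).
#' @return invisibly, the list of written paths.
#' @export
run_simulate <- function(config, out_prefix, profiles = default_profiles()) {
  sim <- simulate_cohort(config, profiles)
  iv <- data.frame(child_id = sim$intervals$child_id,
                   date = format(sim$intervals$date),
                   start = format_hhmm(sim$intervals$start),
                   end = format_hhmm(sim$intervals$end),
                   next_day = as.integer(sim$intervals$end >= 24))
  paths <- paste0(out_prefix, c("intervals.csv", "daily.csv", "children.csv",
                                "labels.csv"))
  write_output_csv(iv, paths[1], config$seed)
  write_output_csv(sim$daily, paths[2], config$seed)
  write_output_csv(sim$children, paths[3], config$seed)
  write_output_csv(sim$labels, paths[4], config$seed)
  msg("simulated %d children (%d sleep intervals, %d clipped draws)",
      nrow(sim$children), nrow(iv), sim$n_clipped)
  invisible(paths)
}

load_cohort_files <- function(intervals, daily, children, labels = NULL,
                              n_days = 14L) {
  iv <- read_intervals(intervals)
  dl <- read_daily_flags(daily)
  ch <- read_children(children)
  lb <- NULL
  if (!is.null(labels)) {
    df <- utils::read.csv(labels, comment.char = "#", stringsAsFactors = FALSE)
    stopifnot_cols(df, c("child_id", "label"), labels)
    lb <- df
  }
  build_cohort(iv, dl, ch, lb, n_days = n_days)
}

#' Run: extract features for a cohort from CSV inputs
#'
#' Wraps [extract_cohort_features()] over the three input tables; per-child
#' failures are logged to standard error and reported, not fatal.
#'
#' @param intervals,daily,children paths to the input CSVs.
#' @param out output features CSV. Bed times on the extended scale (>= 24)
#'   are also rendered as clock strings in `bed_time_clock`.
#' @param seed master seed for the jittered sigmoid fits.
#' @param n_repeats,jitter_eps sigmoid fit settings (see [fit_sigmoid()]).
#' @param max_missing_days validation threshold (see
#'   [extract_cohort_features()]).
#' @param n_days days per log.
#' @return invisibly, the feature data frame.
#' @export
run_features <- function(intervals, daily, children, out, seed = 1L,
                         n_repeats = 100L, jitter_eps = 0.01,
                         max_missing_days = 3L, n_days = 14L) {
  cohort <- load_cohort_files(intervals, daily, children, n_days = n_days)
  res <- extract_cohort_features(cohort, n_repeats, jitter_eps, seed,
                                 max_missing_days)
  if (nrow(res$failures)) {
    for (i in seq_len(nrow(res$failures)))
      msg("skipped child %s: %s", res$failures$child_id[i],
          res$failures$reason[i])
  }
  if (is.null(res$features)) stop("no child yielded features", call. = FALSE)
  feats <- res$features
  feats$bed_time_clock <- format_hhmm(feats$bed_time)
  write_output_csv(feats, out, seed, c(intervals, daily, children))
  msg("features extracted for %d/%d children -> %s", nrow(feats),
      length(cohort$logs), out)
  invisible(feats)
}

#' Run: screen a cohort end to end
#'
#' Reads the cohort tables, extracts features, applies the classifier bank,
#' and writes per-child judgments (`child_id,group_id,y0,y1,margin,label`).
#' Children failing validation or in unsupported age groups are listed in the
#' summary, not silently dropped. Deterministic given `seed`.
#'
#' @inheritParams run_features
#' @param bank path to a bank CSV, or NULL for the packaged published bank.
#' @param out output judgments CSV.
#' @return invisibly, a list with `judgments`, `unsupported`, `failures`,
#'   `counts` (per group and label).
#' @export
run_screen <- function(intervals, daily, children, out, bank = NULL,
                       seed = 1L, n_repeats = 100L, jitter_eps = 0.01,
                       max_missing_days = 3L, n_days = 14L) {
  bk <- load_bank(bank)
  cohort <- load_cohort_files(intervals, daily, children, n_days = n_days)
  res <- extract_cohort_features(cohort, n_repeats, jitter_eps, seed,
                                 max_missing_days)
  if (is.null(res$features)) stop("no child yielded features", call. = FALSE)
  scr <- classify_cohort(res$features, bk)
  write_output_csv(scr$judgments, out, seed,
                   c(intervals, daily, children, bank %||% character(0)))
  counts <- if (nrow(scr$judgments))
    as.data.frame(table(group_id = scr$judgments$group_id,
                        label = scr$judgments$label))
  else NULL
  msg("screened %d children (%d flagged severe); %d unsupported age, %d failed validation/extraction -> %s",
      nrow(scr$judgments), sum(scr$judgments$label == 0L),
      nrow(scr$unsupported), nrow(res$failures), out)
  invisible(list(judgments = scr$judgments, unsupported = scr$unsupported,
                 failures = res$failures, counts = counts))
}

#' Run: train a classifier bank from labeled features
#'
#' @param features path to a features CSV (as written by [run_features()]).
#' @param labels path to a labels CSV (`child_id,label`).
#' @param out_bank output bank CSV (loadable by [load_bank()]).
#' @param out_report output JSON report with per-group statistics, stepwise
#'   traces, and leave-one-out accuracies.
#' @inheritParams train_bank
#' @param seed recorded in output headers (training itself is deterministic).
#' @return invisibly, the [train_bank()] result.
#' @export
run_train <- function(features, labels, out_bank, out_report = NULL,
                      f_enter = 3.84, f_remove = 2.71, max_steps = 20L,
                      priors = c(0.5, 0.5), seed = 1L) {
  fe <- utils::read.csv(features, comment.char = "#", stringsAsFactors = FALSE)
  lb <- utils::read.csv(labels, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot_cols(fe, c("child_id", "age_months", feature_names()), features)
  stopifnot_cols(lb, c("child_id", "label"), labels)
  res <- train_bank(fe, lb, f_enter, f_remove, max_steps, priors)
  if (!length(res$bank))
    stop("training produced no classifier (single-class or empty groups)",
         call. = FALSE)
  write_bank(res$bank, out_bank, header = output_header(seed, c(features, labels)))
  if (!is.null(out_report)) {
    rep <- list(
      header = output_header(seed, c(features, labels)),
      groups = lapply(res$models, function(m) list(
        group_id = m$classifier$group_id, n = m$n, variables = m$selected,
        eigenvalue = m$eigenvalue,
        canonical_correlation = m$canonical_correlation,
        wilks_lambda = m$wilks_lambda, chi_square = m$chi_square,
        df = m$df, p_value = m$p_value, loo_accuracy = m$loo_accuracy,
        trace = m$trace)),
      skipped = res$report$skipped)
    jsonlite::write_json(rep, out_report, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  msg("trained %d group classifier(s) -> %s", length(res$bank), out_bank)
  invisible(res)
}
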