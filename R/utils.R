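# Internal helpers: clock-time parsing, seeded evaluation, small utilities.

EPOCHS_PER_DAY <- 288L     # 5-minute epochs
EPOCH_HOURS <- 1 / 12
DAY_START_HOUR <- 3        # logical day d covers decimal hours [3, 27)
DAY_END_HOUR <- 27

#' Parse "HH:MM" clock strings to decimal hours
#'
#' @param x character vector of "HH:MM" times on a 24-hour clock.
#' @param what label used in error messages.
#' @return numeric vector of decimal hours in [0, 24).
#' @keywords internal
#' @noRd
parse_hhmm <- function(x, what = "time") {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop(sprintf("malformed %s '%s' (row %d): expected 'HH:MM'",
                 what, x[which(bad)[1]], which(bad)[1]), call. = FALSE)
  }
  hh <- vapply(m, function(g) as.numeric(g[2]), numeric(1))
  mm <- vapply(m, function(g) as.numeric(g[3]), numeric(1))
  oor <- hh > 23 | mm > 59
  if (any(oor)) {
    stop(sprintf("out-of-range %s '%s' (row %d): hours must be 00-23, minutes 00-59",
                 what, x[which(oor)[1]], which(oor)[1]), call. = FALSE)
  }
  hh + mm / 60
}

#' Format decimal hours as "HH:MM" (hours taken modulo 24)
#' @keywords internal
#' @noRd
format_hhmm <- function(h) {
  h <- h %% 24
  mins <- round(h * 60)
  sprintf("%02d:%02d", mins %/% 60, mins %% 60)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded internals do not
#' perturb user-level simulations. A NULL seed evaluates as-is.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a per-unit seed from a master seed and a counter
#'
#' Counter-based so per-child results are independent of cohort ordering.
#' Kept below 2^31 - 1.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 16807) %%
               2147483647) + 1L
}

#' Stable non-negative integer counter from a child identifier
#' @keywords internal
#' @noRd
string_counter <- function(id) {
  h <- 0
  for (k in utf8ToInt(as.character(id))) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("'%s': missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
}
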