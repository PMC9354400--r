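# Per-age-group Fisher classification functions: the packaged published
# coefficient bank, age-group assignment, scoring, and the screening decision.

#' Age-group table for pediatric sleep screening
#'
#' Nine developmental age groups covering 0-83 months. Group 0 (0-2 months)
#' has no published classifier (the source cohort was too small at that age),
#' so screening supports groups 1-8.
#'
#' @return data frame with `group_id`, `min_months`, `max_months`, `label`.
#' @export
age_group_table <- function() {
  data.frame(
    group_id = 0:8,
    min_months = c(0L, 3L, 6L, 10L, 15L, 19L, 48L, 60L, 72L),
    max_months = c(2L, 5L, 9L, 14L, 18L, 47L, 59L, 71L, 83L),
    label = c("0-2 m", "3-5 m", "6-9 m", "10-14 m", "15-18 m", "19-47 m",
              "48-59 m", "60-71 m", "72-83 m"),
    stringsAsFactors = FALSE
  )
}

#' Assign ages in months to age groups
#'
#' @param age_months integer vector, 0-83.
#' @return integer vector of group ids (0-8).
#' @export
#' @examples
#' assign_age_group(c(4, 47, 48))
assign_age_group <- function(age_months) {
  age_months <- as.integer(age_months)
  if (any(is.na(age_months) | age_months < 0 | age_months > 83)) {
    bad <- age_months[which(is.na(age_months) | age_months < 0 | age_months > 83)[1]]
    stop(sprintf("unsupported age: %s months (screening covers 0-83 months)",
                 ifelse(is.na(bad), "NA", bad)), call. = FALSE)
  }
  tab <- age_group_table()
  idx <- findInterval(age_months, tab$min_months)
  tab$group_id[idx]
}

# table labels used in the published coefficient listings -> canonical names
variable_label_map <- c(
  "Wake up time" = "wake_up_time",
  "Wake up time variation" = "wake_up_time_variation",
  "Bed time" = "bed_time",
  "Bed time variation" = "bed_time_variation",
  "Total sleep duration" = "total_sleep_duration",
  "Nocturnal sleep duration" = "nocturnal_sleep_duration",
  "Night wakings" = "night_wakings",
  "Evening nap" = "evening_nap",
  "Breakfast" = "breakfast",
  "Self-awake" = "self_awake"
)

canonicalize_variable <- function(v) {
  out <- ifelse(v %in% feature_names(), v,
                unname(variable_label_map[v]))
  if (anyNA(out)) {
    stop(sprintf("unknown discriminant variable '%s'", v[which(is.na(out))[1]]),
         call. = FALSE)
  }
  out
}

#' Load a Fisher classifier bank
#'
#' Reads a bank CSV (`group_id,variable,coef_y0,coef_y1`, with
#' `variable = "(constant)"` rows carrying the intercepts) into a
#' `fisher_bank`. With no `path`, loads the packaged bank transcribed from
#' the published per-age-group coefficient listings (groups 1-8; y0 = severe
#' sleep disorder, y1 = no severe disorder). Note: for group 6 (48-59 months)
#' the published coefficient listing and summary table give wake-up time
#' variation as the second discriminant variable, while the accompanying
#' prose mentions bed time variation; the bank follows the tables.
#'
#' @param path bank CSV; NULL for the packaged published bank.
#' @return object of class `fisher_bank`: named list of classifiers, each
#'   with `group_id`, `variables`, `coef_y0`, `coef_y1`, `const_y0`,
#'   `const_y1`.
#' @export
#' @examples
#' bank <- load_bank()
#' names(bank)
load_bank <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "fisher_bank.csv", package = "somnoscreen",
                        mustWork = TRUE)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot_cols(df, c("group_id", "variable", "coef_y0", "coef_y1"), path)
  bank <- lapply(split(df, df$group_id), function(g) {
    is_const <- g$variable == "(constant)"
    if (sum(is_const) != 1L) {
      stop(sprintf("bank group %s: expected exactly one '(constant)' row",
                   g$group_id[1]), call. = FALSE)
    }
    vars <- canonicalize_variable(g$variable[!is_const])
    list(group_id = as.integer(g$group_id[1]),
         variables = vars,
         coef_y0 = stats::setNames(as.numeric(g$coef_y0[!is_const]), vars),
         coef_y1 = stats::setNames(as.numeric(g$coef_y1[!is_const]), vars),
         const_y0 = as.numeric(g$coef_y0[is_const]),
         const_y1 = as.numeric(g$coef_y1[is_const]))
  })
  names(bank) <- vapply(bank, function(b) as.character(b$group_id), character(1))
  structure(bank, class = "fisher_bank")
}

#' Write a Fisher classifier bank to CSV
#'
#' Inverse of [load_bank()]; coefficients round-trip exactly at the stored
#' precision.
#'
#' @param bank a `fisher_bank`.
#' @param path output CSV path.
#' @param header optional character vector of comment lines (prefixed `#`).
#' @return `path`, invisibly.
#' @export
write_bank <- function(bank, path, header = NULL) {
  num <- function(x) sub("0+$", "", sub("(\\.[0-9]*[1-9])0+$", "\\1",
                                        sprintf("%.17g", x)))
  rows <- do.call(rbind, lapply(bank, function(b) {
    data.frame(group_id = b$group_id,
               variable = c(b$variables, "(constant)"),
               coef_y0 = num(c(unname(b$coef_y0), b$const_y0)),
               coef_y1 = num(c(unname(b$coef_y1), b$const_y1)),
               stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(rows, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.fisher_bank <- function(x, ...) {
  cat(sprintf("<fisher_bank> %d age-group classifier(s)\n", length(x)))
  for (b in x) {
    cat(sprintf("  group %d: %s\n", b$group_id,
                paste(b$variables, collapse = ", ")))
  }
  invisible(x)
}

#' Fisher classification scores
#'
#' Evaluates the two linear classification functions
#' y_g = sum(coef_g * features) + const_g for g in {0 = severe disorder,
#' 1 = no severe disorder}.
#'
#' @param classifier one element of a `fisher_bank`.
#' @param features named numeric vector, list, or one-row data frame holding
#'   at least the classifier's variables.
#' @return named numeric `c(y0, y1)`.
#' @export
#' @examples
#' fisher_scores(load_bank()[["1"]], c(bed_time = 21.0))
fisher_scores <- function(classifier, features) {
  if (!is.list(features)) features <- as.list(features)
  v <- vapply(classifier$variables, function(nm) {
    val <- features[[nm]]
    if (is.null(val) || is.na(val)) {
      stop(sprintf("feature '%s' required by group-%d classifier is missing",
                   nm, classifier$group_id), call. = FALSE)
    }
    as.numeric(val)
  }, numeric(1))
  c(y0 = sum(classifier$coef_y0 * v) + classifier$const_y0,
    y1 = sum(classifier$coef_y1 * v) + classifier$const_y1)
}

#' Screen one child's features with the classifier bank
#'
#' Assigns the age group, evaluates the group's Fisher functions, and returns
#' the judgment: label 1 (no severe sleep disorder) iff y1 > y0, else label 0
#' (severe sleep disorder, immediate intervention advised). Ties are labeled
#' 0, the conservative screening default. Ages in group 0 (0-2 months) have
#' no published classifier and raise an error advising clinical review.
#'
#' @param features named numeric vector/list/one-row data frame of features.
#' @param age_months child age in months.
#' @param bank a `fisher_bank` (default: packaged published bank).
#' @param child_id optional identifier carried into the result.
#' @return one-row data frame `child_id, group_id, y0, y1, margin, label`.
#' @export
#' @examples
#' classify(c(bed_time = 21.0), age_months = 4)
classify <- function(features, age_months, bank = load_bank(),
                     child_id = NA_character_) {
  gid <- assign_age_group(age_months)
  cl <- bank[[as.character(gid)]]
  if (is.null(cl)) {
    stop(sprintf(
      "no classifier for age group %d (%s months): refer to clinical review",
      gid, paste(age_group_table()$label[gid + 1])), call. = FALSE)
  }
  s <- fisher_scores(cl, features)
  data.frame(child_id = child_id, group_id = gid,
             y0 = unname(s["y0"]), y1 = unname(s["y1"]),
             margin = unname(s["y1"] - s["y0"]),
             label = as.integer(s["y1"] > s["y0"]),
             stringsAsFactors = FALSE)
}

#' Screen a table of extracted features
#'
#' Vector version of [classify()]: children in unsupported age groups are
#' reported separately, not silently dropped.
#'
#' @param features data frame with `child_id`, `age_months`, and the feature
#'   columns (as produced by [extract_cohort_features()]).
#' @param bank a `fisher_bank`.
#' @return list with `judgments` (data frame) and `unsupported`
#'   (data frame `child_id,age_months,reason`).
#' @export
classify_cohort <- function(features, bank = load_bank()) {
  jud <- list()
  uns <- list()
  for (i in seq_len(nrow(features))) {
    row <- tryCatch(
      classify(features[i, , drop = FALSE], features$age_months[i], bank,
               child_id = features$child_id[i]),
      error = function(e) e)
    if (inherits(row, "error")) {
      uns[[length(uns) + 1L]] <- data.frame(
        child_id = features$child_id[i],
        age_months = features$age_months[i],
        reason = conditionMessage(row), stringsAsFactors = FALSE)
    } else {
      jud[[length(jud) + 1L]] <- row
    }
  }
  list(judgments = if (length(jud)) do.call(rbind, jud) else
         data.frame(child_id = character(0), group_id = integer(0),
                    y0 = numeric(0), y1 = numeric(0), margin = numeric(0),
                    label = integer(0)),
       unsupported = if (length(uns)) do.call(rbind, uns) else
         data.frame(child_id = character(0), age_months = integer(0),
                    reason = character(0)))
}
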