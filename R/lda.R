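# Two-group linear discriminant analysis with stepwise Wilks'-lambda variable
# selection, Fisher classification functions, Bartlett's chi-square, and
# leave-one-out accuracy. Group 0 of the label convention is the severe class
# (judgment 0), group 1 the non-severe class.

as_feature_matrix <- function(x, vars = NULL) {
  x <- as.data.frame(x)
  if (is.null(vars)) vars <- colnames(x)
  m <- as.matrix(x[, vars, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("feature matrix contains missing values", call. = FALSE)
  m
}

check_labels <- function(labels, n) {
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels length mismatch", call. = FALSE)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes (0 and 1) must be present", call. = FALSE)
  labels
}

# pooled within-group and total scatter (SSCP) matrices
scatter_matrices <- function(m, labels) {
  tot <- crossprod(scale(m, center = TRUE, scale = FALSE))
  within <- matrix(0, ncol(m), ncol(m), dimnames = dimnames(tot))
  for (g in c(0L, 1L)) {
    mg <- m[labels == g, , drop = FALSE]
    within <- within + crossprod(scale(mg, center = TRUE, scale = FALSE))
  }
  list(W = within, T = tot, B = tot - within)
}

#' Wilks' lambda for a variable subset
#'
#' Lambda = det(W) / det(T), the ratio of the pooled within-group scatter
#' determinant to the total scatter determinant; smaller values indicate
#' better group separation.
#'
#' @param x data frame or matrix of features (rows = children).
#' @param labels binary class labels (0 = severe, 1 = non-severe).
#' @param vars variable subset (default: all columns).
#' @return Lambda in (0, 1].
#' @export
#' @examples
#' wilks_lambda(data.frame(v = c(1, 2, 3, 4)), labels = c(0, 0, 1, 1))
wilks_lambda <- function(x, labels, vars = NULL) {
  m <- as_feature_matrix(x, vars)
  labels <- check_labels(labels, nrow(m))
  s <- scatter_matrices(m, labels)
  dW <- det(s$W)
  dT <- det(s$T)
  if (!is.finite(dW) || !is.finite(dT) || dT <= 0 || dW <= 0)
    stop("singular scatter matrix for the requested variable subset", call. = FALSE)
  dW / dT
}

# partial F statistic for a change in Wilks' lambda (two-group case):
# entering at current model size p: F = (n - g - p) * (L_p / L_{p+1} - 1)
partial_f <- function(lambda_before, lambda_after, n, p_after, g = 2L) {
  (n - g - p_after + 1L) / (g - 1L) * (lambda_before / lambda_after - 1)
}

#' Stepwise variable selection minimizing Wilks' lambda
#'
#' At each step the candidate that minimizes the overall Wilks' lambda is
#' entered if its partial F-to-enter reaches `f_enter`; after each entry,
#' included variables whose partial F-to-remove falls below `f_remove` are
#' removed. Selection stops when no action qualifies or after `max_steps`
#' actions. Variables with pooled within-group variance below `var_tol` are
#' excluded from candidacy (and reported) to guard against singular scatter.
#'
#' @inheritParams wilks_lambda
#' @param f_enter F threshold to enter (default 3.84).
#' @param f_remove F threshold to remove (default 2.71).
#' @param max_steps maximum number of enter/remove actions (default 20).
#' @param var_tol pooled within-group variance tolerance (default 1e-12).
#' @return object of class `stepwise_trace`: list with `selected` (character),
#'   `trace` (data frame `step,action,variable,lambda,F`), `dropped`
#'   (near-constant variables excluded up front).
#' @export
stepwise_select <- function(x, labels, f_enter = 3.84, f_remove = 2.71,
                            max_steps = 20L, var_tol = 1e-12) {
  m <- as_feature_matrix(x)
  labels <- check_labels(labels, nrow(m))
  n <- nrow(m)
  g <- 2L

  pooled_var <- vapply(colnames(m), function(v) {
    sum(vapply(c(0L, 1L), function(cl) {
      xv <- m[labels == cl, v]
      sum((xv - mean(xv))^2)
    }, numeric(1))) / (n - g)
  }, numeric(1))
  dropped <- names(pooled_var)[pooled_var < var_tol]
  candidates <- setdiff(colnames(m), dropped)

  selected <- character(0)
  lambda_cur <- 1
  trace <- data.frame(step = integer(0), action = character(0),
                      variable = character(0), lambda = numeric(0),
                      F = numeric(0), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (step >= max_steps) break
    acted <- FALSE

    # entry: candidate minimizing lambda, admitted if F-to-enter >= f_enter
    avail <- setdiff(candidates, selected)
    if (length(avail) && n - g - length(selected) >= 1L) {
      lams <- vapply(avail, function(v) {
        tryCatch(wilks_lambda(m, labels, c(selected, v)),
                 error = function(e) NA_real_)
      }, numeric(1))
      if (any(is.finite(lams))) {
        best <- avail[which.min(lams)]
        lam_new <- min(lams, na.rm = TRUE)
        f <- partial_f(lambda_cur, lam_new, n, length(selected) + 1L)
        if (is.finite(f) && f >= f_enter) {
          selected <- c(selected, best)
          lambda_cur <- lam_new
          step <- step + 1L
          trace <- rbind(trace, data.frame(step = step, action = "enter",
                                           variable = best, lambda = lam_new,
                                           F = f, stringsAsFactors = FALSE))
          acted <- TRUE
        }
      }
    }

    # removal: any included variable whose F-to-remove is below f_remove
    if (length(selected) > 1L && step < max_steps) {
      repeat {
        fs <- vapply(selected, function(v) {
          lam_wo <- wilks_lambda(m, labels, setdiff(selected, v))
          partial_f(lam_wo, lambda_cur, n, length(selected))
        }, numeric(1))
        worst <- selected[which.min(fs)]
        if (min(fs) >= f_remove || step >= max_steps) break
        selected <- setdiff(selected, worst)
        lambda_cur <- wilks_lambda(m, labels, selected)
        step <- step + 1L
        trace <- rbind(trace, data.frame(step = step, action = "remove",
                                         variable = worst, lambda = lambda_cur,
                                         F = min(fs), stringsAsFactors = FALSE))
        acted <- TRUE
        if (length(selected) <= 1L) break
      }
    }
    if (!acted) break
  }
  structure(list(selected = selected, trace = trace, dropped = dropped,
                 lambda = if (length(selected)) lambda_cur else 1,
                 n = n),
            class = "stepwise_trace")
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat(sprintf("<stepwise_trace> %d step(s); selected: %s\n", nrow(x$trace),
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(none)"))
  if (nrow(x$trace)) print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Fit the two-group canonical discriminant
#'
#' Computes the discriminant eigenvalue (largest eigenvalue of W^-1 B),
#' Wilks' lambda, and the canonical correlation, which in the two-group case
#' satisfy Lambda = 1/(1 + eigenvalue) and R^2 = eigenvalue/(1 + eigenvalue).
#'
#' @inheritParams wilks_lambda
#' @return list with `variables`, `eigenvalue`, `canonical_correlation`,
#'   `wilks_lambda`, `coefficients` (canonical discriminant coefficients,
#'   scaled to unit pooled within-group variance), `n`.
#' @export
fit_lda <- function(x, labels, vars = NULL) {
  m <- as_feature_matrix(x, vars)
  labels <- check_labels(labels, nrow(m))
  s <- scatter_matrices(m, labels)
  WiB <- tryCatch(solve(s$W, s$B), error = function(e)
    stop("singular within-group scatter matrix", call. = FALSE))
  ev <- eigen(WiB, only.values = FALSE)
  lambda1 <- Re(ev$values[1])
  a <- Re(ev$vectors[, 1])
  n <- nrow(m)
  # scale so the canonical variate has unit pooled within-group variance
  a <- a / sqrt(drop(t(a) %*% s$W %*% a) / (n - 2))
  list(variables = colnames(m),
       eigenvalue = lambda1,
       canonical_correlation = sqrt(lambda1 / (1 + lambda1)),
       wilks_lambda = 1 / (1 + lambda1),
       coefficients = stats::setNames(a, colnames(m)),
       n = n)
}

#' Bartlett's chi-square test of the discriminant function
#'
#' chi^2 = -(n - 1 - (p + g)/2) * ln(Lambda) with df = p (g - 1); for the
#' two-group case df equals the number of discriminant variables.
#'
#' @param lambda Wilks' lambda in (0, 1].
#' @param n total sample size.
#' @param p number of discriminant variables.
#' @param g number of groups (default 2).
#' @return list with `chi_square`, `df`, `p_value`.
#' @export
#' @examples
#' bartlett_chi_square(0.614, n = 37, p = 1)
bartlett_chi_square <- function(lambda, n, p, g = 2L) {
  stopifnot(lambda > 0, lambda <= 1)
  mult <- n - 1 - (p + g) / 2
  if (mult <= 0) stop("sample too small for Bartlett's chi-square", call. = FALSE)
  chi <- -mult * log(lambda)
  df <- p * (g - 1L)
  list(chi_square = chi, df = df,
       p_value = stats::pchisq(chi, df, lower.tail = FALSE))
}

#' Fisher classification functions from training data
#'
#' One linear scoring function per class: coefficients S^-1 mu_g and constant
#' -mu_g' S^-1 mu_g / 2 + log(prior_g), with S the pooled within-group
#' covariance. A case is assigned to the class with the larger score.
#'
#' @inheritParams wilks_lambda
#' @param priors length-2 prior probabilities for classes (0, 1);
#'   default equal.
#' @param group_id optional age-group id stored on the classifier.
#' @return classifier list compatible with [fisher_scores()] (`variables`,
#'   `coef_y0`, `coef_y1`, `const_y0`, `const_y1`, `group_id`).
#' @export
fisher_functions <- function(x, labels, vars = NULL, priors = c(0.5, 0.5),
                             group_id = NA_integer_) {
  m <- as_feature_matrix(x, vars)
  labels <- check_labels(labels, nrow(m))
  stopifnot(length(priors) == 2, all(priors > 0))
  priors <- priors / sum(priors)
  n <- nrow(m)
  s <- scatter_matrices(m, labels)
  S <- s$W / (n - 2)
  Sinv_mu <- function(mu) tryCatch(solve(S, mu), error = function(e)
    stop("singular pooled within-group covariance", call. = FALSE))
  mu0 <- colMeans(m[labels == 0L, , drop = FALSE])
  mu1 <- colMeans(m[labels == 1L, , drop = FALSE])
  c0 <- Sinv_mu(mu0)
  c1 <- Sinv_mu(mu1)
  list(group_id = group_id,
       variables = colnames(m),
       coef_y0 = stats::setNames(c0, colnames(m)),
       coef_y1 = stats::setNames(c1, colnames(m)),
       const_y0 = -0.5 * sum(mu0 * c0) + log(priors[1]),
       const_y1 = -0.5 * sum(mu1 * c1) + log(priors[2]))
}

classify_rows <- function(classifier, m) {
  y0 <- m %*% classifier$coef_y0 + classifier$const_y0
  y1 <- m %*% classifier$coef_y1 + classifier$const_y1
  as.integer(y1 > y0)
}

#' Leave-one-out cross-validated accuracy
#'
#' For each case, Fisher classification functions are refitted on the
#' remaining n - 1 cases and the held-out case is classified; the returned
#' accuracy is the fraction classified correctly.
#'
#' @inheritParams fisher_functions
#' @return fraction in [0, 1].
#' @export
loo_accuracy <- function(x, labels, vars = NULL, priors = c(0.5, 0.5)) {
  m <- as_feature_matrix(x, vars)
  labels <- check_labels(labels, nrow(m))
  n <- nrow(m)
  if (n < 4) stop("need at least 4 cases for leave-one-out", call. = FALSE)
  if (min(table(labels)) < 2)
    stop("a fold would have a single-class training set", call. = FALSE)
  correct <- logical(n)
  for (i in seq_len(n)) {
    cl <- fisher_functions(m[-i, , drop = FALSE], labels[-i], priors = priors)
    correct[i] <- classify_rows(cl, m[i, , drop = FALSE]) == labels[i]
  }
  mean(correct)
}

#' Train a full discriminant model for one group
#'
#' Stepwise Wilks'-lambda selection followed by the canonical fit, Bartlett's
#' chi-square, Fisher classification functions, and leave-one-out accuracy.
#'
#' @inheritParams stepwise_select
#' @inheritParams fisher_functions
#' @return object of class `lda_model`: list with `selected`, `trace`,
#'   `eigenvalue`, `canonical_correlation`, `wilks_lambda`, `chi_square`,
#'   `df`, `p_value`, `classifier`, `loo_accuracy`, `n`.
#' @export
train_lda_model <- function(x, labels, f_enter = 3.84, f_remove = 2.71,
                            max_steps = 20L, priors = c(0.5, 0.5),
                            group_id = NA_integer_) {
  sel <- stepwise_select(x, labels, f_enter, f_remove, max_steps)
  if (!length(sel$selected)) {
    return(structure(list(selected = character(0), trace = sel$trace,
                          dropped = sel$dropped, n = sel$n,
                          classifier = NULL,
                          note = "no variable met the entry criterion"),
                     class = "lda_model"))
  }
  fit <- fit_lda(x, labels, sel$selected)
  bart <- bartlett_chi_square(fit$wilks_lambda, fit$n, length(sel$selected))
  cl <- fisher_functions(x, labels, sel$selected, priors, group_id)
  structure(list(selected = sel$selected, trace = sel$trace,
                 dropped = sel$dropped,
                 eigenvalue = fit$eigenvalue,
                 canonical_correlation = fit$canonical_correlation,
                 wilks_lambda = fit$wilks_lambda,
                 canonical_coefficients = fit$coefficients,
                 chi_square = bart$chi_square, df = bart$df,
                 p_value = bart$p_value,
                 classifier = cl,
                 loo_accuracy = loo_accuracy(x, labels, sel$selected, priors),
                 n = fit$n),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  if (is.null(x$classifier)) {
    cat("<lda_model> empty selection:", x$note, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<lda_model> n = %d; variables: %s\n  eigenvalue %.3f, canonical R %.3f, Wilks' lambda %.3f\n  chi-square %.2f (df %d, p %.3g); LOO accuracy %.1f%%\n",
    x$n, paste(x$selected, collapse = ", "), x$eigenvalue,
    x$canonical_correlation, x$wilks_lambda, x$chi_square, x$df, x$p_value,
    100 * x$loo_accuracy))
  invisible(x)
}

#' Train a classifier bank from labeled cohort features
#'
#' Runs the per-age-group training pipeline for groups 1-8 (group 0 is not
#' trained: screening at 0-2 months is referred to clinical review). Groups
#' lacking both classes, or where no variable meets the entry criterion, are
#' skipped and reported.
#'
#' @param features data frame with `child_id`, `age_months`, and the ten
#'   feature columns.
#' @param labels binary labels aligned with `features` rows (or a data frame
#'   `child_id,label`).
#' @inheritParams train_lda_model
#' @return list with `bank` (a `fisher_bank`), `models` (per-group
#'   `lda_model`), and `report` (per-group summary data frame plus skip
#'   reasons).
#' @export
train_bank <- function(features, labels, f_enter = 3.84, f_remove = 2.71,
                       max_steps = 20L, priors = c(0.5, 0.5)) {
  if (is.data.frame(labels)) {
    labels <- as.integer(labels$label)[match(features$child_id, labels$child_id)]
  }
  gid <- assign_age_group(features$age_months)
  models <- list()
  skipped <- list()
  for (g in 1:8) {
    idx <- which(gid == g)
    lab <- labels[idx]
    if (length(idx) < 4 || length(unique(lab)) < 2) {
      skipped[[as.character(g)]] <- sprintf(
        "group %d skipped: n = %d, classes present = %d", g, length(idx),
        length(unique(lab)))
      next
    }
    mod <- train_lda_model(features[idx, feature_names(), drop = FALSE], lab,
                           f_enter, f_remove, max_steps, priors, group_id = g)
    if (is.null(mod$classifier)) {
      skipped[[as.character(g)]] <- sprintf("group %d skipped: %s", g, mod$note)
      next
    }
    models[[as.character(g)]] <- mod
  }
  bank <- structure(lapply(models, function(m) m$classifier),
                    class = "fisher_bank")
  report <- do.call(rbind, lapply(models, function(m) data.frame(
    group_id = m$classifier$group_id, n = m$n,
    n_variables = length(m$selected),
    variables = paste(m$selected, collapse = ";"),
    eigenvalue = m$eigenvalue,
    canonical_correlation = m$canonical_correlation,
    wilks_lambda = m$wilks_lambda, chi_square = m$chi_square, df = m$df,
    p_value = m$p_value, loo_accuracy = m$loo_accuracy,
    stringsAsFactors = FALSE)))
  list(bank = bank, models = models,
       report = list(summary = report, skipped = unlist(skipped)))
}
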