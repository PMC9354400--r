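test_that("Wilks' lambda matches hand computation and bounds", {
  # groups {1,2} vs {3,4}: SSW = 1, SST = 5
  expect_equal(wilks_lambda(data.frame(v = c(1, 2, 3, 4)), c(0, 0, 1, 1)), 0.2)
  # identical group means: no between-group scatter
  expect_equal(wilks_lambda(data.frame(v = c(1, 2, 1, 2)), c(0, 0, 1, 1)), 1.0)
  set.seed(3)
  for (r in 1:20) {
    m <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
    L <- wilks_lambda(m, rep(0:1, 10))
    expect_gt(L, 0)
    expect_lte(L, 1 + 1e-12)
  }
})

test_that("fit_lda satisfies the two-group eigenvalue identities", {
  f <- fit_lda(data.frame(v = c(1, 2, 3, 4)), c(0, 0, 1, 1))
  expect_equal(f$eigenvalue, 4, tolerance = 1e-10)
  expect_equal(f$canonical_correlation, sqrt(4 / 5), tolerance = 1e-10)
  expect_equal(f$wilks_lambda, 0.2, tolerance = 1e-10)
  f2 <- fit_lda(data.frame(v = c(1, 2, 1, 2)), c(0, 0, 1, 1))
  expect_equal(f2$eigenvalue, 0, tolerance = 1e-10)
  expect_equal(f2$canonical_correlation, 0, tolerance = 1e-7)
})

test_that("Bartlett chi-square matches the published statistics from printed inputs", {
  expect_equal(bartlett_chi_square(1, n = 100, p = 3)$chi_square, 0)
  ref <- published_group_stats()
  for (i in seq_len(nrow(ref))) {
    lam <- 1 / (1 + ref$eigenvalue[i])
    b <- bartlett_chi_square(lam, n = ref$n[i], p = ref$df[i])
    expect_equal(b$df, ref$df[i])
    expect_lt(abs(b$chi_square - ref$chi_square[i]) / ref$chi_square[i], 0.002)
  }
  expect_error(bartlett_chi_square(0.5, n = 3, p = 4), "too small")
})

test_that("Fisher functions match the 1-D closed form", {
  # sample means 0 and 1, pooled variance exactly 1, equal priors
  x <- data.frame(v = c(-1, 0, 1, 0, 1, 2))
  lb <- c(0, 0, 0, 1, 1, 1)
  cl <- fisher_functions(x, lb)
  expect_equal(unname(cl$coef_y0), 0, tolerance = 1e-12)
  expect_equal(unname(cl$coef_y1), 1, tolerance = 1e-12)
  expect_equal(cl$const_y0, log(0.5), tolerance = 1e-12)
  expect_equal(cl$const_y1, -0.5 + log(0.5), tolerance = 1e-12)
  # decision boundary at x = 0.5
  s_lo <- fisher_scores(cl, c(v = 0.49))
  s_hi <- fisher_scores(cl, c(v = 0.51))
  expect_lt(s_lo["y1"], s_lo["y0"])
  expect_gt(s_hi["y1"], s_hi["y0"])
})

test_that("equal group means give identical coefficients; priors decide", {
  x <- data.frame(v = c(1, 2, 1, 2))
  cl <- fisher_functions(x, c(0, 0, 1, 1), priors = c(0.9, 0.1))
  expect_equal(cl$coef_y0, cl$coef_y1)
  expect_equal(cl$const_y0 - cl$const_y1, log(0.9) - log(0.1))
})

test_that("lambda matches brute-force determinant ratio and Fisher matches Mahalanobis", {
  set.seed(5)
  for (r in 1:200) {
    p <- sample(1:3, 1)
    n <- sample(10:50, 1)
    lb <- c(rep(0, floor(n / 2)), rep(1, ceiling(n / 2)))
    m <- matrix(rnorm(n * p), n, p) + outer(lb, rnorm(p))
    colnames(m) <- paste0("v", 1:p)
    expect_lt(abs(wilks_lambda(m, lb) - wilks_oracle(m, lb)), 1e-10)

    cl <- fisher_functions(m, lb)
    pred <- as.integer((m %*% cl$coef_y1 + cl$const_y1) >
                         (m %*% cl$coef_y0 + cl$const_y0))
    S <- (crossprod(scale(m[lb == 0, , drop = FALSE], scale = FALSE)) +
            crossprod(scale(m[lb == 1, , drop = FALSE], scale = FALSE))) / (n - 2)
    d0 <- stats::mahalanobis(m, colMeans(m[lb == 0, , drop = FALSE]), S)
    d1 <- stats::mahalanobis(m, colMeans(m[lb == 1, , drop = FALSE]), S)
    expect_equal(pred, as.integer(d1 < d0))
  }
})

test_that("stepwise selection finds the informative variable first", {
  set.seed(8)
  n <- 200
  lb <- rep(0:1, each = n / 2)
  m <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("v", 1:6)))
  m[lb == 1, 3] <- m[lb == 1, 3] + 3  # group means 3 SD apart on v3 only
  sel <- stepwise_select(m, lb)
  expect_equal(sel$trace$variable[1], "v3")
  expect_equal(sel$trace$action[1], "enter")
  # oracle: v3 has the smallest single-variable lambda
  lams <- vapply(colnames(m), function(v) wilks_lambda(m, lb, v), numeric(1))
  expect_equal(names(which.min(lams)), "v3")
})

test_that("all-noise matrices usually yield empty selections at f_enter = 3.84", {
  set.seed(9)
  empty <- vapply(1:50, function(r) {
    m <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("v", 1:5)))
    length(stepwise_select(m, rep(0:1, 30))$selected) == 0
  }, logical(1))
  expect_gt(mean(empty), 0.5)
})

test_that("stepwise traces are bounded and lambda non-increasing over entries", {
  set.seed(10)
  for (r in 1:20) {
    m <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(NULL, paste0("v", 1:6)))
    lb <- rep(0:1, 40)
    m[lb == 1, ] <- m[lb == 1, ] + matrix(rnorm(6, 0, 0.6), 40, 6, byrow = TRUE)
    sel <- stepwise_select(m, lb)
    expect_lte(nrow(sel$trace), 20)
    ent <- sel$trace[sel$trace$action == "enter", ]
    if (nrow(ent) > 1) expect_true(all(diff(ent$lambda) <= 1e-12))
  }
})

test_that("near-constant variables are dropped before selection", {
  m <- cbind(v1 = c(rnorm(20), rnorm(20) + 2), v2 = rep(1, 40))
  sel <- stepwise_select(m, rep(0:1, each = 20))
  expect_equal(sel$dropped, "v2")
  expect_equal(sel$selected, "v1")
})

test_that("leave-one-out accuracy matches enumeration, nulls, and separation", {
  # well-separated clusters
  set.seed(14)
  m <- cbind(v = c(rnorm(20), rnorm(20) + 10))
  expect_equal(loo_accuracy(m, rep(0:1, each = 20)), 1.0)

  # 6-point hand dataset: per-fold brute force with the same closed form
  x <- c(0, 1, 2, 3, 10, 11)
  lb <- c(0, 0, 0, 1, 1, 1)
  brute <- vapply(1:6, function(i) {
    xt <- x[-i]; lt <- lb[-i]
    mu <- c(mean(xt[lt == 0]), mean(xt[lt == 1]))
    s2 <- (sum((xt[lt == 0] - mu[1])^2) + sum((xt[lt == 1] - mu[2])^2)) / 3
    y <- mu / s2 * x[i] - mu^2 / (2 * s2) + log(0.5)
    as.integer(y[2] > y[1]) == lb[i]
  }, logical(1))
  expect_equal(loo_accuracy(cbind(v = x), lb), mean(brute))

  # permutation null: accuracy near the majority-class rate
  set.seed(15)
  m <- matrix(rnorm(200 * 2), 200, 2, dimnames = list(NULL, c("a", "b")))
  lb <- sample(rep(0:1, each = 100))
  expect_lt(abs(loo_accuracy(m, lb) - 0.5), 0.1)
})

test_that("leave-one-out matches an independent cross-validated LDA", {
  skip_if_not_installed("MASS")
  set.seed(16)
  n <- 80
  m <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("v", 1:3)))
  lb <- rep(0:1, each = 40)
  m[lb == 1, 1] <- m[lb == 1, 1] + 1.5
  cv <- MASS::lda(m, grouping = lb, prior = c(0.5, 0.5), CV = TRUE)
  expect_equal(loo_accuracy(m, lb), mean(cv$class == lb))
})

test_that("LOO accuracy recovers the analytic Bayes accuracy for a known shift", {
  set.seed(13)
  n <- 800
  delta <- 1.0
  m <- cbind(v1 = c(rnorm(n), rnorm(n) + delta), v2 = rnorm(2 * n))
  lb <- rep(0:1, each = n)
  acc <- loo_accuracy(m, lb, vars = "v1")
  expect_lt(abs(acc - pnorm(delta / 2)), 0.05)
})

test_that("train_bank fits per-group models and skips degenerate groups", {
  set.seed(18)
  mk_group <- function(g, n, sep) {
    ages <- age_group_table()
    f <- as.data.frame(matrix(rnorm(n * 10, 0, 0.3), n, 10,
                              dimnames = list(NULL, feature_names())))
    f$bed_time <- 21.4 + rnorm(n, 0, 0.3)
    lab <- rep(0:1, length.out = n)
    f$bed_time[lab == 0] <- f$bed_time[lab == 0] + sep
    cbind(data.frame(child_id = sprintf("g%d_%03d", g, 1:n),
                     age_months = ages$min_months[g + 1]), f, label = lab)
  }
  dat <- do.call(rbind, lapply(1:8, mk_group, n = 60, sep = 2))
  # group 2 gets one class only: must be skipped
  dat$label[dat$age_months == age_group_table()$min_months[3]] <- 1L
  res <- train_bank(dat[, c("child_id", "age_months", feature_names())],
                    dat[, c("child_id", "label")])
  expect_named(res$bank, as.character(c(1, 3:8)))
  expect_match(res$report$skipped[["2"]], "classes present = 1")
  for (m in res$models) {
    expect_equal(m$trace$variable[1], "bed_time")
    expect_gte(m$loo_accuracy, 0.9)
    expect_lte(nrow(m$trace), 20)
  }
  # retrained bank round-trips through the bank file format
  f <- tempfile(fileext = ".csv")
  write_bank(res$bank, f)
  expect_equal(load_bank(f), res$bank, tolerance = 0)
  # and is directly usable for classification
  j <- classify(c(bed_time = 21.4), age_months = 4, bank = res$bank)
  expect_true(j$label %in% c(0L, 1L))
})

test_that("single-class input is a structured error", {
  expect_error(wilks_lambda(data.frame(v = 1:4), c(1, 1, 1, 1)),
               "both classes")
})
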