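# small random regression problem with named columns
rand_problem <- function(n = 20, p = 3, seed = 1, noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("c%d", 1:p)))
  beta <- rnorm(p)
  list(X = X, y = as.numeric(2 + X %*% beta + rnorm(n, 0, noise)))
}

test_that("single-column solutions follow the soft-threshold closed form", {
  # standardised column with (1/n) x'(y - ybar) = 1
  X <- cbind(f = c(1, -1))
  y <- c(2, 0)
  m <- lasso_fit(X, y, 0.4)
  # population sd of the column is 1, so scales coincide
  expect_equal(unname(m$coefficients), 0.6, tolerance = 1e-6)
  expect_equal(m$intercept, 1, tolerance = 1e-6)
  m0 <- lasso_fit(X, y, 1.5)           # above lambda_max = 1
  expect_equal(unname(m0$coefficients), 0)
  expect_equal(m0$intercept, mean(y))
})

test_that("the unpenalised lasso equals ordinary least squares", {
  pr <- rand_problem(20, 3)
  m <- lasso_fit(pr$X, pr$y, 0)
  ols <- coef(lm(pr$y ~ pr$X))
  expect_equal(unname(c(m$intercept, m$coefficients)), unname(ols),
               tolerance = 1e-5)
  expect_equal(predict(m, pr$X),
               unname(cbind(1, pr$X) %*% ols)[, 1], tolerance = 1e-5)
})

test_that("at and above lambda_max every coefficient is zero", {
  pr <- rand_problem(30, 6, seed = 2)
  g <- lambda_grid(pr$X, pr$y)
  expect_equal(max(g), g[1])  # descending
  m <- lasso_fit(pr$X, pr$y, g[1])
  expect_true(all(m$coefficients == 0))
  expect_equal(m$intercept, mean(pr$y))
  just_below <- lasso_fit(pr$X, pr$y, g[1] * 0.99)
  expect_true(any(just_below$coefficients != 0))
})

test_that("KKT optimality holds at returned solutions on random instances", {
  for (s in 1:10) {
    pr <- rand_problem(25, 8, seed = s, noise = 0.5)
    lam <- runif(1, 0.05, 0.5)
    m <- lasso_fit(pr$X, pr$y, lam)
    kkt <- kkt_residuals(pr$X, pr$y, m)
    std_coef <- kkt$coefficient * m$scale[kkt$column]
    zero <- std_coef == 0
    expect_true(all(abs(kkt$gradient[zero]) <= lam + 1e-5))
    if (any(!zero)) {
      expect_true(all(abs(abs(kkt$gradient[!zero]) - lam) <= 1e-5))
      expect_true(all(sign(kkt$gradient[!zero]) == sign(std_coef[!zero])))
    }
  }
})

test_that("lasso solutions match an independent implementation", {
  skip_if_not_installed("glmnet")
  pr <- rand_problem(40, 10, seed = 4, noise = 0.5)
  lams <- c(0.8, 0.4, 0.15, 0.05)
  fit <- glmnet::glmnet(pr$X, pr$y, lambda = lams, thresh = 1e-12,
                        standardize = TRUE)
  for (i in seq_along(lams)) {
    m <- lasso_fit(pr$X, pr$y, lams[i])
    expect_equal(unname(m$coefficients), unname(fit$beta[, i]),
                 tolerance = 1e-4)
    expect_equal(m$intercept, unname(fit$a0[i]), tolerance = 1e-4)
  }
})

test_that("the penalty grid spans lambda_max down to the ratio exactly", {
  X <- cbind(f = c(1, -1))
  expect_equal(max(lambda_grid(X, c(2, 0))), 1)
  g <- lambda_grid(rand_problem(30, 4, 3)$X, rand_problem(30, 4, 3)$y,
                   n_lambda = 50, ratio = 0.05)
  expect_length(g, 50)
  expect_true(all(diff(g) < 0))
  expect_equal(g[50] / g[1], 0.05, tolerance = 1e-12)
  degen <- lambda_grid(cbind(f = c(1, -1, 0)), rep(5, 3))
  expect_true(isTRUE(attr(degen, "degenerate")))
})

test_that("constant responses and zero-variance columns degrade gracefully", {
  X <- cbind(a = c(1, 0, 1, 0), b = rep(1, 4))
  expect_warning(m <- lasso_fit(X, c(3, 3, 3, 3), 0.1), "zero-variance")
  expect_true(all(m$coefficients == 0))
  expect_equal(m$intercept, 3)
})

test_that("the number of active coefficients shrinks towards lambda_max", {
  pr <- rand_problem(40, 10, seed = 6, noise = 1)
  g <- lambda_grid(pr$X, pr$y, n_lambda = 30)
  fit <- plasmapattern:::lasso_path(pr$X, pr$y, g)
  nnz <- colSums(fit$beta != 0)
  # path ordered large -> small lambda; support grows as lambda decreases
  expect_equal(nnz[1], 0)
  expect_true(all(diff(nnz[1:10]) >= 0))
})

test_that("repeated cross-validation is deterministic and finds real signal", {
  set.seed(20)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, sprintf("c%d", 1:5)))
  y <- as.numeric(6 * X[, 1])
  cv1 <- cv_select_lambda(X, y, folds = 10, repeats = 3, seed = 7)
  cv2 <- cv_select_lambda(X, y, folds = 10, repeats = 3, seed = 7)
  expect_identical(cv1, cv2)
  expect_true(cv1$lambda_min %in% cv1$lambda_grid)
  m <- lasso_fit(X, y, cv1$lambda_min)
  expect_true(m$coefficients["c1"] != 0)
  expect_error(cv_select_lambda(X[1:5, ], y[1:5], folds = 10), "folds")
})

test_that("pure-noise features keep the cross-validated model nearly empty", {
  sparse_picks <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    X <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(NULL, sprintf("c%d", 1:20)))
    y <- rnorm(50)
    cv <- cv_select_lambda(X, y, folds = 10, repeats = 3, seed = s)
    m <- lasso_fit(X, y, cv$lambda_min)
    sum(m$coefficients != 0)
  }, numeric(1))
  expect_gte(mean(sparse_picks <= 2), 0.8)
})

test_that("median absolute error follows the order-statistic conventions", {
  expect_equal(median_absolute_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(median_absolute_error(c(1, 2, 10), c(2, 2, 2)), 1)
  expect_equal(median_absolute_error(c(0, 0, 0, 0), c(1, 2, 3, 4)), 2.5)
  expect_error(median_absolute_error(1:3, 1:4), "length")
})

test_that("stability selection reduces to a single CV fit when degenerate", {
  set.seed(30)
  X <- matrix(rbinom(40 * 8, 1, 0.5), 40, 8,
              dimnames = list(NULL, sprintf("P%d", 1:8)))
  y <- as.numeric(25 + 6 * X[, 1] - 4 * X[, 2] + rnorm(40, 0, 0.5))
  st <- suppressWarnings(
    stability_select(X, y, iterations = 1, fraction = 1, folds = 5,
                     repeats = 2, seed = 9))
  expect_equal(st$consensus, sort(st$per_iteration_selected[[1]]))
  expect_true(is.na(st$mae["holdout_pooled"]))  # nothing held out
  st_a <- stability_select(X, y, iterations = 4, fraction = 0.9, folds = 5,
                           repeats = 2, seed = 11)
  st_b <- stability_select(X, y, iterations = 4, fraction = 0.9, folds = 5,
                           repeats = 2, seed = 11)
  expect_identical(st_a, st_b)
  # the evaluation wrapper reports the corresponding stability MAE
  expect_equal(evaluate_mae(X, y, method = "holdout_pooled", iterations = 4,
                            fraction = 0.9, folds = 5, repeats = 2, seed = 11),
               unname(st_a$mae["holdout_pooled"]))
  # consensus is contained in every iteration's selection
  for (sel in st_a$per_iteration_selected)
    expect_true(all(st_a$consensus %in% sel))
})

test_that("strong binary signal is recovered with small error; noise is refused", {
  set.seed(31)
  X <- matrix(rbinom(104 * 10, 1, 0.5), 104, 10,
              dimnames = list(NULL, sprintf("P%d", 1:10)))
  y <- as.numeric(30 + 5 * X[, 1] - 5 * X[, 2])   # noiseless
  st <- stability_select(X, y, iterations = 5, folds = 10, repeats = 2,
                         seed = 3)
  expect_true(all(c("P1", "P2") %in% st$consensus))
  expect_lt(st$mae[["holdout_pooled"]], 0.5)
  expect_lt(st$mae[["refit_insample"]], 0.5)
  # all-noise features: holdout MAE near the intercept-only baseline
  ratio <- vapply(1:6, function(s) {
    set.seed(100 + s)
    y2 <- rnorm(104, 30, 4)
    st2 <- suppressWarnings(
      stability_select(X, y2, iterations = 5, folds = 10, repeats = 2,
                       seed = s))
    st2$mae[["holdout_pooled"]] / median(abs(y2 - mean(y2)))
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.2)
})

test_that("in-sample error is optimistic relative to pooled holdout on average", {
  gaps <- vapply(1:10, function(s) {
    set.seed(400 + s)
    X <- matrix(rbinom(60 * 15, 1, 0.5), 60, 15,
                dimnames = list(NULL, sprintf("P%d", 1:15)))
    y <- as.numeric(30 + 3 * X[, 1] - 2 * X[, 2] + rnorm(60))
    st <- suppressWarnings(
      stability_select(X, y, iterations = 5, folds = 5, repeats = 2,
                       seed = s))
    st$mae[["holdout_pooled"]] - st$mae[["refit_insample"]]
  }, numeric(1))
  expect_gt(mean(gaps), 0)
})
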