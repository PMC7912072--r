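# BMI prediction from binary protein occurrence: L1-penalised linear
# regression (cyclic coordinate descent, compiled core), repeated-CV
# lambda selection, subsample-intersection stability selection and
# median-absolute-error evaluation.

# Column standardisation for penalised fitting: centre everything, scale
# by the population sd (n denominator). Zero-variance columns are
# reported via `keep`.
standardize_columns <- function(X, standardize = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  center <- colMeans(X)
  sdev <- sqrt(pmax(colMeans(X^2) - center^2, 0))
  keep <- sdev > 1e-10
  sc <- if (standardize) sdev else rep(1, ncol(X))
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, center[keep]), 2,
              sc[keep], "/")
  list(Xs = Xs, center = center, scale = sc, keep = keep)
}

# Pathwise lasso over a non-increasing lambda sequence. Returns original
# 0/1-scale coefficients (zero rows for dropped columns).
lasso_path <- function(X, y, lambdas, standardize = TRUE,
                       tol = 1e-7, maxit = 100000L, warn_dropped = TRUE) {
  std <- standardize_columns(X, standardize)
  if (warn_dropped && !all(std$keep))
    warning("dropping zero-variance column(s): ",
            paste(colnames(X)[!std$keep], collapse = ", "))
  n <- nrow(X)
  p <- ncol(X)
  ybar <- mean(y)
  beta <- matrix(0, p, length(lambdas),
                 dimnames = list(colnames(X), NULL))
  if (any(std$keep) && sd(y) > 0) {
    Cm <- crossprod(std$Xs) / n
    g <- as.numeric(crossprod(std$Xs, y - ybar)) / n
    B <- lasso_cd_path(Cm, g, lambdas, tol, as.integer(maxit))
    beta[std$keep, ] <- B / std$scale[std$keep]
  }
  a0 <- ybar - as.numeric(crossprod(beta, std$center))
  list(lambda = lambdas, a0 = a0, beta = beta,
       center = std$center, scale = std$scale, keep = std$keep)
}

#' Fit an L1-penalised linear regression at one penalty value
#'
#' Minimises `(1/2n) sum (y_i - b0 - x_i b)^2 + lambda * sum |b_j|` by
#' cyclic coordinate descent on column-standardised features (centred,
#' scaled by the population sd), with coefficients back-transformed to
#' the original 0/1 feature scale. Zero-variance columns are dropped
#' with a warning; a constant response yields an intercept-only model.
#'
#' @param X numeric (typically binary) feature matrix with colnames.
#' @param y numeric response (BMI, kg/m^2), length `nrow(X)`.
#' @param lambda penalty weight, >= 0.
#' @param standardize scale columns to unit population sd before
#'   penalising (default TRUE).
#' @param tol convergence tolerance on the standardised-scale
#'   coefficient change (default 1e-7).
#' @param maxit coordinate-descent iteration cap.
#' @return a `lasso_model`: intercept, named coefficient vector on the
#'   original feature scale, lambda, and the standardisation record.
#' @export
lasso_fit <- function(X, y, lambda, standardize = TRUE,
                      tol = 1e-7, maxit = 100000L) {
  stopifnot(nrow(X) >= 2, length(y) == nrow(X), lambda >= 0)
  fit <- lasso_path(X, y, lambda, standardize, tol, maxit)
  structure(list(intercept = fit$a0[1],
                 coefficients = fit$beta[, 1],
                 lambda = lambda,
                 center = fit$center, scale = fit$scale, keep = fit$keep,
                 standardize = standardize),
            class = "lasso_model")
}

#' @export
predict.lasso_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  cf <- object$coefficients
  if (!is.null(colnames(newdata)) && !is.null(names(cf)))
    newdata <- newdata[, names(cf), drop = FALSE]
  as.numeric(object$intercept + newdata %*% cf)
}

#' Penalty grid for the lasso path
#'
#' `lambda_max` is the smallest penalty at which every coefficient is
#' zero, `max_j |x_j'(y - ybar)| / n` over standardised columns; the
#' grid is log-spaced from `lambda_max` down to `lambda_max * ratio`.
#'
#' @inheritParams lasso_fit
#' @param n_lambda grid size (default 100).
#' @param ratio smallest/largest penalty ratio (default 0.01).
#' @return strictly decreasing numeric vector; a zero-signal problem
#'   returns `0` with attribute `degenerate = TRUE`.
#' @export
lambda_grid <- function(X, y, n_lambda = 100, ratio = 0.01,
                        standardize = TRUE) {
  stopifnot(n_lambda >= 2)
  std <- standardize_columns(X, standardize)
  lambda_max <- if (any(std$keep))
    max(abs(crossprod(std$Xs, y - mean(y)))) / nrow(X) else 0
  if (lambda_max == 0)
    return(structure(0, degenerate = TRUE))
  exp(seq(log(lambda_max), log(lambda_max * ratio), length.out = n_lambda))
}

#' Select lambda by repeated k-fold cross-validation
#'
#' For each repeat a fresh random fold assignment is drawn; per lambda,
#' the out-of-fold prediction error (squared by default) is averaged
#' over every held-out sample across all folds and repeats, and
#' `lambda_min` is the grid value with the minimum average error, ties
#' broken toward the larger (sparser) lambda.
#'
#' @inheritParams lambda_grid
#' @param folds number of CV folds (default 10).
#' @param repeats number of CV repetitions (default 10).
#' @param seed RNG seed for the fold assignments.
#' @param metric "mse" (default) or "mae" out-of-fold error.
#' @param tol coordinate-descent tolerance for the fold fits; the CV
#'   curve is insensitive below 1e-5, so fold fits use that by default
#'   while final models keep the tighter 1e-7.
#' @return a `cv_result`: lambda_grid, mean_cv_error, lambda_min, folds,
#'   repeats.
#' @export
cv_select_lambda <- function(X, y, folds = 10, repeats = 10, seed = 1,
                             n_lambda = 100, ratio = 0.01,
                             metric = c("mse", "mae"), standardize = TRUE,
                             tol = 1e-5) {
  metric <- match.arg(metric)
  n <- nrow(X)
  if (n < folds) stop("need at least as many samples as folds")
  grid <- lambda_grid(X, y, n_lambda, ratio, standardize)
  err_sum <- numeric(length(grid))
  err_n <- 0
  set.seed(seed)
  for (r in seq_len(repeats)) {
    assign <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      test <- which(assign == f)
      train <- which(assign != f)
      if (length(test) < 1 || length(train) < 2)
        stop("cross-validation fold with too few samples")
      fit <- lasso_path(X[train, , drop = FALSE], y[train], grid,
                        standardize, tol = tol, warn_dropped = FALSE)
      pred <- X[test, , drop = FALSE] %*% fit$beta +
        rep(fit$a0, each = length(test))
      e <- if (metric == "mse") (pred - y[test])^2 else abs(pred - y[test])
      err_sum <- err_sum + colSums(e)
      err_n <- err_n + length(test)
    }
  }
  mean_err <- err_sum / err_n
  structure(list(lambda_grid = as.numeric(grid),
                 mean_cv_error = mean_err,
                 lambda_min = grid[which.min(mean_err)],
                 folds = folds, repeats = repeats, metric = metric),
            class = "cv_result")
}

#' Stability selection by subsample intersection
#'
#' Repeats the whole lambda-selection-and-fit procedure on random
#' subsamples (default: 10 iterations on 90% of the samples, drawn
#' without replacement). Each iteration records the proteins with
#' nonzero coefficients at its CV-selected lambda; the consensus set is
#' the intersection over all iterations ("selected 10 out of 10 times").
#' The final model is refit on all samples restricted to the consensus
#' proteins, with its own CV-selected lambda (or an OLS refit).
#' Held-out samples of each iteration are predicted with that
#' iteration's model and pooled for the holdout MAE.
#'
#' @inheritParams cv_select_lambda
#' @param iterations number of subsample iterations (default 10).
#' @param fraction subsample fraction (default 0.9);
#'   `floor(fraction * n)` samples are drawn without replacement.
#' @param final "cv" (lasso with fresh CV lambda, default) or "ols".
#' @return a `stability_result`: per-iteration selections, consensus
#'   set, final model, holdout predictions and both MAE protocols.
#' @export
stability_select <- function(X, y, iterations = 10, fraction = 0.9,
                             folds = 10, repeats = 10, seed = 1,
                             n_lambda = 100, ratio = 0.01,
                             metric = "mse", standardize = TRUE,
                             final = c("cv", "ols")) {
  final <- match.arg(final)
  n <- nrow(X)
  m <- floor(fraction * n)
  if (m < folds) stop("subsample smaller than the number of CV folds")
  set.seed(seed)
  iter_seeds <- sample.int(10^9, iterations + 1)
  selected <- vector("list", iterations)
  lambdas <- numeric(iterations)
  holdout <- vector("list", iterations)
  for (i in seq_len(iterations)) {
    set.seed(iter_seeds[i])
    idx <- sample.int(n, m)
    cv <- cv_select_lambda(X[idx, , drop = FALSE], y[idx], folds, repeats,
                           seed = iter_seeds[i] + 1L, n_lambda = n_lambda,
                           ratio = ratio, metric = metric,
                           standardize = standardize)
    fit <- suppressWarnings(
      lasso_fit(X[idx, , drop = FALSE], y[idx], cv$lambda_min,
                standardize = standardize))
    selected[[i]] <- names(fit$coefficients)[fit$coefficients != 0]
    lambdas[i] <- cv$lambda_min
    out <- setdiff(seq_len(n), idx)
    if (length(out))
      holdout[[i]] <- data.frame(
        iteration = i, index = out,
        truth = y[out],
        predicted = predict(fit, X[out, , drop = FALSE]))
  }
  consensus <- sort(Reduce(intersect, selected))
  holdout <- do.call(rbind, holdout)
  empty <- length(consensus) == 0
  if (empty) {
    final_model <- structure(list(intercept = mean(y),
                                  coefficients = setNames(numeric(0), character(0)),
                                  lambda = NA_real_),
                             class = "lasso_model")
    cv_final <- NULL
    warning("empty consensus set; final model is intercept-only")
  } else if (final == "cv") {
    Xc <- X[, consensus, drop = FALSE]
    cv_final <- cv_select_lambda(Xc, y, folds, repeats,
                                 seed = iter_seeds[iterations + 1],
                                 n_lambda = n_lambda, ratio = ratio,
                                 metric = metric, standardize = standardize)
    final_model <- suppressWarnings(
      lasso_fit(Xc, y, cv_final$lambda_min, standardize = standardize))
  } else {
    Xc <- X[, consensus, drop = FALSE]
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xc), y)
    final_model <- structure(list(intercept = fit$coefficients[1],
                                  coefficients = fit$coefficients[-1],
                                  lambda = 0),
                             class = "lasso_model")
    cv_final <- NULL
  }
  insample <- if (empty) rep(mean(y), n)
              else predict(final_model, X[, consensus, drop = FALSE])
  mae <- c(
    holdout_pooled = if (is.null(holdout)) NA_real_ else
      median_absolute_error(holdout$truth, holdout$predicted),
    refit_insample = median_absolute_error(y, insample))
  structure(list(iterations = iterations, fraction = fraction,
                 per_iteration_selected = selected,
                 per_iteration_lambda = lambdas,
                 consensus = consensus, empty_consensus = empty,
                 final_model = final_model, cv_final = cv_final,
                 holdout = holdout, mae = mae, seed = seed),
            class = "stability_result")
}

#' Median absolute prediction error
#'
#' `median(|y_true - y_pred|)`; for an even number of samples the mean
#' of the two central order statistics.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 1.
#' @return MAE in the units of `y` (kg/m^2 for BMI).
#' @export
median_absolute_error <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!length(y_true)) stop("empty input")
  median(abs(y_true - y_pred))
}

#' Evaluate BMI prediction error under a stated protocol
#'
#' `holdout_pooled` (default): each stability iteration's model predicts
#' that iteration's ~10% held-out samples; all held-out (true,
#' predicted) pairs are pooled and their MAE returned. `refit_insample`:
#' MAE of the final consensus model's in-sample predictions.
#'
#' @inheritParams stability_select
#' @param method evaluation protocol.
#' @return MAE in kg/m^2.
#' @export
evaluate_mae <- function(X, y, method = c("holdout_pooled", "refit_insample"),
                         ...) {
  method <- match.arg(method)
  res <- stability_select(X, y, ...)
  unname(res$mae[method])
}

#' Karush-Kuhn-Tucker residual correlations of a lasso solution
#'
#' Returns, per retained column, `(1/n) x_j'(y - yhat)` on the
#' standardised scale together with the coefficient, for optimality
#' checking: the absolute value must not exceed lambda for zero
#' coefficients and must equal lambda (matching the coefficient sign)
#' for nonzero ones.
#'
#' @param X,y the data the model was fit on.
#' @param model a `lasso_model`.
#' @return data frame: column, coefficient, gradient.
#' @export
kkt_residuals <- function(X, y, model) {
  std <- standardize_columns(X, model$standardize)
  r <- y - predict(model, X)
  grad <- as.numeric(crossprod(std$Xs, r)) / nrow(X)
  data.frame(column = colnames(X)[std$keep],
             coefficient = model$coefficients[std$keep],
             gradient = grad,
             stringsAsFactors = FALSE)
}
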