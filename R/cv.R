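#' Regression metrics for age prediction
#'
#' MAE, R-squared, RMSE and MAPE of predicted vs. chronological age:
#' `MAE = mean |y - yhat|`, `R2 = 1 - SSE/SST`, `RMSE = sqrt(mean (y -
#' yhat)^2)`, `MAPE = 100 * mean |(y - yhat)/y|`.
#'
#' @param y observed ages (> 0 for MAPE).
#' @param yhat predicted ages, same length.
#' @return Named numeric vector `mae`, `r2`, `rmse`, `mape`.
#' @examples
#' evaluate_predictions(c(10, 20, 40), c(12, 18, 46))
#' @export
evaluate_predictions <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) > 0)
  if (any(y == 0)) stop("MAPE undefined for zero ages")
  err <- y - yhat
  sst <- sum((y - mean(y))^2)
  c(mae = mean(abs(err)),
    r2 = 1 - sum(err^2) / sst,
    rmse = sqrt(mean(err^2)),
    mape = 100 * mean(abs(err / y)))
}

# mean +/- 1.96 SD/sqrt(k) over fold-level metric values
fold_ci <- function(vals) {
  k <- length(vals)
  m <- mean(vals)
  half <- 1.96 * stats::sd(vals) / sqrt(k)
  c(mean = m, lo = m - half, hi = m + half)
}

# Min-max scaler to [-1, 1]; parameters from the training rows only.
fit_scaler <- function(X) {
  rng <- apply(X, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  span[span == 0] <- 1
  list(min = rng[1L, ], span = span)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2L, scaler$min, "-"), 2L, scaler$span / 2, "/") - 1
}

# Seeded partition into k folds of near-equal size (sizes differ by <= 1).
make_folds <- function(n, k, seed) {
  if (k > n) stop("more folds than samples")
  withr_seed(seed, {
    fold <- rep(seq_len(k), length.out = n)
    sample(fold)
  })
}

#' K-fold cross-validated age prediction
#'
#' Seeded random partition into `k` folds; per fold, a min-max scaler is fit
#' on the training rows only, the network is trained on the scaled training
#' data and evaluated on the held-out fold.  Metrics are reported per fold
#' (with normal-approximation 95% CIs over folds) and pooled over the
#' concatenated out-of-fold predictions.
#'
#' @param X subjects x feature matrix (raw scale).
#' @param y ages.
#' @param k number of folds (default 10).
#' @param seed integer seed (partition and per-fold network init).
#' @param trainer `function(X, y, seed) -> model` with a `predict` method;
#'   defaults to a committee of [train_lm()] restarts (see `committee`).
#' @param committee size of the default committee: `committee` networks are
#'   trained from different seeded initializations and their predictions
#'   averaged, then clipped to the training age range.  Averaging restarts
#'   tames the run-to-run variance of Levenberg-Marquardt on small
#'   over-parameterized networks; `committee = 1` trains a single net.
#' @param ... passed on to the default trainer.
#' @return An object of class `"cv_result"`: `pooled` metrics, `per_fold`
#'   matrix, `ci` (per metric), `predictions` data frame, `folds`, `seed`.
#' @export
kfold_cv <- function(X, y, k = 10L, seed = 1L, trainer = NULL,
                     committee = 3L, ...) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (is.null(trainer))
    trainer <- function(X, y, seed)
      fcnn_committee(X, y, n_nets = committee, seed = seed, ...)
  folds <- make_folds(nrow(X), k, seed)
  yhat <- rep(NA_real_, length(y))
  per_fold <- matrix(NA_real_, k, 4L,
                     dimnames = list(NULL, c("mae", "r2", "rmse", "mape")))
  for (f in seq_len(k)) {
    te <- folds == f
    scaler <- fit_scaler(X[!te, , drop = FALSE])
    model <- trainer(apply_scaler(X[!te, , drop = FALSE], scaler), y[!te],
                     seed = seed + f)
    yhat[te] <- stats::predict(model, apply_scaler(X[te, , drop = FALSE], scaler))
    per_fold[f, ] <- evaluate_predictions(y[te], yhat[te])
  }
  ci <- apply(per_fold, 2L, fold_ci)
  structure(list(pooled = evaluate_predictions(y, yhat),
                 per_fold = per_fold, ci = ci,
                 predictions = data.frame(y = y, yhat = yhat, fold = folds),
                 folds = folds, seed = seed),
            class = "cv_result")
}

#' Committee of restart-trained networks
#'
#' Trains `n_nets` networks by [train_lm()] from different seeded
#' initializations (sharing the validation split) and predicts with their
#' average, clipped to the training target range.
#'
#' @inheritParams train_lm
#' @param n_nets committee size.
#' @param ... further arguments to [train_lm()].
#' @return An object of class `"fcnn_committee"`.
#' @export
fcnn_committee <- function(X, y, n_nets = 3L, seed = 1L, ...) {
  nets <- lapply(seq_len(n_nets), function(i)
    train_lm(X, y, n_starts = 1L, seed = seed + 7919L * (i - 1L), ...))
  structure(list(nets = nets, y_range = range(y)), class = "fcnn_committee")
}

#' @export
predict.fcnn_committee <- function(object, newdata, ...) {
  ph <- rowMeans(vapply(object$nets, function(n)
    predict.net_params(n, newdata), numeric(nrow(as.matrix(newdata)))))
  pmin(pmax(ph, object$y_range[1L]), object$y_range[2L])
}

#' @export
print.fcnn_committee <- function(x, ...) {
  cat(sprintf("Committee of %d LM-trained networks (%s)\n", length(x$nets),
              paste(x$nets[[1L]]$sizes, collapse = "-")))
  invisible(x)
}

#' @export
print.cv_result <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("10-fold CV (k=%d): MAE %.2f y, R2 %.3f, RMSE %.2f y, MAPE %.1f%%\n",
              nrow(x$per_fold), p["mae"], p["r2"], p["rmse"], p["mape"]))
  cat(sprintf("  MAE 95%% CI over folds: [%.2f, %.2f]\n",
              x$ci["lo", "mae"], x$ci["hi", "mae"]))
  invisible(x)
}

#' Baseline regressors under identical folds
#'
#' Linear regression, support vector regression, ridge regression and random
#' forest evaluated with exactly the same fold partition and scaling
#' protocol as the network, for reference comparisons.
#'
#' @inheritParams kfold_cv
#' @param methods subset of `c("linear", "svr", "ridge", "rf")`.
#' @return List of class `"baseline_table"`: `metrics` (method x metric
#'   pooled values) and the shared `folds`.
#' @export
baselines <- function(X, y, k = 10L, seed = 1L,
                      methods = c("linear", "svr", "ridge", "rf")) {
  methods <- match.arg(methods, several.ok = TRUE)
  X <- as.matrix(X); y <- as.numeric(y)
  folds <- make_folds(nrow(X), k, seed)
  res <- matrix(NA_real_, length(methods), 4L,
                dimnames = list(methods, c("mae", "r2", "rmse", "mape")))
  for (m in methods) {
    yhat <- rep(NA_real_, length(y))
    for (f in seq_len(k)) {
      te <- folds == f
      scaler <- fit_scaler(X[!te, , drop = FALSE])
      Xtr <- apply_scaler(X[!te, , drop = FALSE], scaler)
      Xte <- apply_scaler(X[te, , drop = FALSE], scaler)
      ytr <- y[!te]
      yhat[te] <- switch(
        m,
        linear = {
          df_tr <- as.data.frame(Xtr); names(df_tr) <- paste0("V", seq_len(ncol(Xtr)))
          df_te <- as.data.frame(Xte); names(df_te) <- names(df_tr)
          fit <- stats::lm(ytr ~ ., data = cbind(ytr = ytr, df_tr))
          unname(stats::predict(fit, df_te))
        },
        svr = {
          fit <- e1071::svm(Xtr, ytr)
          unname(stats::predict(fit, Xte))
        },
        ridge = {
          fit <- withr_seed(seed, glmnet::cv.glmnet(Xtr, ytr, alpha = 0))
          as.numeric(stats::predict(fit, Xte, s = "lambda.min"))
        },
        rf = {
          fit <- withr_seed(seed + f, randomForest::randomForest(Xtr, ytr))
          unname(stats::predict(fit, Xte))
        })
    }
    res[m, ] <- evaluate_predictions(y, yhat)
  }
  structure(list(metrics = res, folds = folds, seed = seed),
            class = "baseline_table")
}

#' @export
print.baseline_table <- function(x, ...) {
  cat("Baseline regressors (pooled 10-fold CV):\n")
  print(round(x$metrics, 3))
  invisible(x)
}
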