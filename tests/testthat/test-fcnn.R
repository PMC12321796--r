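test_that("input assembly produces the documented layouts", {
  cohort <- make_cohort(cohort_config(n = 5L, seed = 41L))
  models <- fit_cohort_spectra(cohort$spectra)
  osf <- build_osf_table(models, cohort$spectra)
  odc <- odc_cohort(osf, 2^-6, 0.1)
  fused <- assemble_input(osf, odc, "fused")
  expect_equal(dim(fused$matrix), c(5L, 390L))
  expect_equal(nrow(fused$layout), 390L)
  expect_equal(sum(fused$layout$block == "osf"), 234L)
  expect_equal(sum(fused$layout$block == "odc"), 156L)
  expect_equal(dim(assemble_input(osf, NULL, "osf")$matrix), c(5L, 234L))
  expect_equal(dim(assemble_input(osf, odc, "odc")$matrix), c(5L, 156L))
  expect_error(assemble_input(osf, NULL, "fused"), "ODC")
  # permutation alignment: row s of the fused matrix is subject s in both blocks
  expect_equal(fused$matrix[3, 1:234],
               assemble_input(osf, NULL, "osf")$matrix[3, ],
               ignore_attr = TRUE)
  expect_equal(fused$matrix[3, 235:390],
               assemble_input(osf, odc, "odc")$matrix[3, ],
               ignore_attr = TRUE)
  # first OSF block entries are the 18 electrodes of feature 1
  expect_equal(unname(fused$matrix[2, 1:18]), unname(osf[2, , 1]))
  # first ODC block entries are row 1 of the subject's dependency matrix
  expect_equal(unname(fused$matrix[2, 235:246]), unname(odc[2, 1, ]))
})

test_that("LM training fits noiseless linear targets and is deterministic", {
  set.seed(3)
  X <- matrix(runif(200 * 5, -1, 1), 200)
  y <- 3 * X[, 1] - 2 * X[, 3] + 0.5 * X[, 5] + 20
  net <- train_lm(X, y, max_epochs = 200L, val_frac = 0, n_starts = 1L,
                  seed = 2L)
  expect_lt(mean(abs(y - predict(net, X))), 0.1)
  # zero-epoch config returns the seeded initialization
  net0 <- train_lm(X, y, max_epochs = 0L, seed = 4L)
  expect_equal(net0$W, fcnn_init(5L, seed = 4L)$W)
  expect_equal(attr(net0, "epochs"), 0L)
  # determinism
  n1 <- train_lm(X, y, max_epochs = 15L, seed = 5L)
  n2 <- train_lm(X, y, max_epochs = 15L, seed = 5L)
  expect_identical(n1$W, n2$W)
  expect_identical(n1$b, n2$b)
})

test_that("LM steps interpolate between Gauss-Newton and gradient descent", {
  # quadratic toy residual: e = y - X theta, J = X constant
  set.seed(10)
  X <- matrix(rnorm(40 * 3), 40)
  theta0 <- c(1, -1, 2)
  y <- X %*% c(3, 0.5, -2)
  e <- as.numeric(y - X %*% theta0)
  J <- X
  gn <- solve(crossprod(J), crossprod(J, e))          # Gauss-Newton step
  grad <- crossprod(J, e)
  for (mu in c(1e-8, 1e8)) {
    delta <- solve(crossprod(J) + diag(mu, 3), grad)
    if (mu < 1) expect_equal(as.numeric(delta), as.numeric(gn),
                             tolerance = 1e-6)
    else expect_equal(as.numeric(delta), as.numeric(grad / mu),
                      tolerance = 1e-6)
  }
  # dual form equals primal form
  mu <- 0.1
  primal <- solve(crossprod(J) + diag(mu, 3), crossprod(J, e))
  dual <- crossprod(J, solve(tcrossprod(J) + diag(mu, 40), e))
  expect_equal(as.numeric(primal), as.numeric(dual), tolerance = 1e-8)
})

test_that("network Jacobian matches finite differences", {
  set.seed(21)
  net <- fcnn_init(4L, hidden = c(3L, 3L, 3L), seed = 21L)
  X <- matrix(runif(6 * 4, -1, 1), 6)
  A <- neoba:::fcnn_forward(net, X)
  J <- neoba:::fcnn_jacobian(net, A)
  th <- neoba:::params_to_vec(net)
  eps <- 1e-6
  for (k in sample(length(th), 10)) {
    thp <- th; thp[k] <- thp[k] + eps
    thm <- th; thm[k] <- thm[k] - eps
    fp <- predict(neoba:::vec_to_params(thp, net), X)
    fm <- predict(neoba:::vec_to_params(thm, net), X)
    expect_equal(J[, k], (fp - fm) / (2 * eps), tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("metric formulas match the hand-computed example", {
  m <- evaluate_predictions(c(10, 20, 40), c(12, 18, 46))
  expect_equal(unname(m["mae"]), 10 / 3, tolerance = 1e-12)
  expect_equal(unname(m["rmse"]), sqrt(44 / 3), tolerance = 1e-12)
  expect_equal(unname(m["mape"]), 15, tolerance = 1e-12)
  expect_equal(unname(m["r2"]), 1 - 44 / (1400 / 3), tolerance = 1e-12)
  perfect <- evaluate_predictions(c(10, 20, 40), c(10, 20, 40))
  expect_equal(unname(perfect), c(0, 1, 0, 0))
  # predicting the mean gives R2 = 0
  ybar <- evaluate_predictions(c(10, 20, 40), rep(70 / 3, 3))
  expect_equal(unname(ybar["r2"]), 0, tolerance = 1e-12)
  expect_error(evaluate_predictions(c(0, 1), c(1, 1)), "zero ages")
})

test_that("metric identities hold on random prediction sets", {
  set.seed(33)
  for (i in 1:10) {
    y <- runif(50, 5, 95)
    yhat <- y + rnorm(50, 0, 5)
    m <- evaluate_predictions(y, yhat)
    expect_gte(m[["rmse"]], m[["mae"]])
    expect_equal(m[["r2"]], 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-12)
  }
})

test_that("fold partitions are balanced, exhaustive, and seeded", {
  f <- neoba:::make_folds(83L, 10L, seed = 2L)
  expect_length(f, 83L)
  expect_lte(diff(range(table(f))), 1L)
  expect_setequal(unique(f), 1:10)
  expect_identical(f, neoba:::make_folds(83L, 10L, seed = 2L))
  expect_error(neoba:::make_folds(5L, 10L, seed = 1L), "more folds")
})

test_that("scaler parameters derive only from training rows", {
  set.seed(12)
  X <- matrix(rnorm(60 * 4), 60)
  tr_rows <- 1:40
  sc <- neoba:::fit_scaler(X[tr_rows, ])
  # mutation test: corrupting a held-out row must not change the scaler
  X2 <- X; X2[55, ] <- 1e6
  sc2 <- neoba:::fit_scaler(X2[tr_rows, ])
  expect_identical(sc, sc2)
  # but corrupting a training row must
  X3 <- X; X3[5, ] <- 1e6
  sc3 <- neoba:::fit_scaler(X3[tr_rows, ])
  expect_false(identical(sc, sc3))
  # scaling maps training values into [-1, 1]
  Z <- neoba:::apply_scaler(X[tr_rows, ], sc)
  expect_gte(min(Z), -1 - 1e-12)
  expect_lte(max(Z), 1 + 1e-12)
})

test_that("cross-validation pools out-of-fold predictions", {
  set.seed(9)
  X <- matrix(runif(120 * 6, -1, 1), 120)
  y <- 40 + 15 * X[, 1] - 10 * X[, 2] + rnorm(120, 0, 1)
  cv <- kfold_cv(X, y, k = 5L, seed = 3L, max_epochs = 30L, committee = 2L)
  expect_equal(nrow(cv$per_fold), 5L)
  expect_false(anyNA(cv$predictions$yhat))
  expect_gt(cv$pooled["r2"], 0.8)
  expect_equal(sort(unique(cv$predictions$fold)), 1:5)
  # every subject predicted exactly once
  expect_equal(nrow(cv$predictions), 120L)
})

test_that("baselines share folds and behave sanely at the extremes", {
  set.seed(14)
  X <- matrix(runif(80 * 4, -1, 1), 80)
  y <- 30 + 10 * X[, 1] + 5 * X[, 2]
  b <- baselines(X, y, k = 5L, seed = 2L, methods = c("linear", "rf"))
  expect_identical(b$folds, neoba:::make_folds(80L, 5L, seed = 2L))
  # exact linear data: linear regression is near-perfect
  expect_lt(b$metrics["linear", "mae"], 1e-6)
  # pure-noise target: random forest cannot explain it
  set.seed(15)
  ynoise <- runif(80, 20, 60)
  bn <- baselines(X, ynoise, k = 5L, seed = 2L, methods = "rf")
  expect_lte(bn$metrics["rf", "r2"], 0.1)
})
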