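#' Assemble the model input matrix from OSF and ODC blocks
#'
#' Concatenates, per subject, the electrode-major flattened OSF block
#' (18 x 13 = 234 values) and the row-major flattened ODC block
#' (13 x 12 = 156 values); the fused layout has 390 dimensions.  Min-max
#' scaling parameters are *not* fit here -- they are fit per training fold
#' inside [kfold_cv()] to avoid leakage.
#'
#' @param osf an [build_osf_table()] result.
#' @param odc an [odc_cohort()] result (required for modes `"odc"` and
#'   `"fused"`).
#' @param mode `"osf"`, `"odc"` or `"fused"`.
#' @return List of class `"feature_input"`: `matrix` (subjects x p),
#'   `layout` (data frame describing each column: block, electrode/row,
#'   feature/col, group).
#' @export
assemble_input <- function(osf, odc = NULL, mode = c("fused", "osf", "odc")) {
  mode <- match.arg(mode)
  stopifnot(inherits(osf, "osf_table"))
  d <- dim(osf)
  fn <- dimnames(osf)[[3L]]
  grp <- osf_feature_groups()
  blocks <- list(); layouts <- list()
  if (mode %in% c("fused", "osf")) {
    # electrode-major: for each feature, the 18 electrodes contiguous
    X_osf <- matrix(aperm(osf, c(1L, 2L, 3L)), nrow = d[1L])
    blocks$osf <- X_osf
    layouts$osf <- data.frame(
      block = "osf",
      electrode = rep(dimnames(osf)[[2L]], times = d[3L]),
      feature = rep(fn, each = d[2L]),
      group = rep(unname(grp[fn]), each = d[2L]),
      stringsAsFactors = FALSE)
  }
  if (mode %in% c("fused", "odc")) {
    if (is.null(odc)) stop("mode requires ODC matrices for every subject")
    stopifnot(inherits(odc, "odc_cohort"))
    do <- dim(odc)
    if (do[1L] != d[1L]) stop("ODC subjects do not match OSF subjects")
    # row-major: for each target row, its 12 coefficients contiguous
    X_odc <- matrix(aperm(odc, c(1L, 3L, 2L)), nrow = do[1L])
    blocks$odc <- X_odc
    layouts$odc <- data.frame(
      block = "odc",
      electrode = NA_character_,
      feature = rep(fn, each = do[3L]),
      group = "ODC",
      stringsAsFactors = FALSE)
  }
  X <- do.call(cbind, blocks)
  layout <- do.call(rbind, layouts)
  rownames(layout) <- NULL
  structure(list(matrix = X, layout = layout, mode = mode),
            class = "feature_input")
}

# --- network primitives ------------------------------------------------------

#' Initialize network parameters
#'
#' Fully connected architecture: input -> 10 -> 10 -> 10 -> 1 with tanh
#' (tansig) hidden units and a linear output.  Weights are drawn uniformly
#' from [-0.5, 0.5] scaled by `1/sqrt(fan_in)` (biases unscaled) so the
#' tanh units start in their linear range even for wide inputs; an
#' unscaled init saturates the first layer when hundreds of inputs feed 10
#' units and stalls training.
#'
#' @param n_in input dimension.
#' @param hidden integer vector of hidden-layer widths.
#' @param seed integer seed.
#' @return List of class `"net_params"` with `W` and `b` per layer.
#' @export
fcnn_init <- function(n_in, hidden = c(10L, 10L, 10L), seed = 1L) {
  sizes <- c(n_in, hidden, 1L)
  withr_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1L)) {
      W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -0.5, 0.5) /
                         sqrt(sizes[l]),
                       sizes[l], sizes[l + 1L])
      b[[l]] <- stats::runif(sizes[l + 1L], -0.5, 0.5)
    }
    structure(list(W = W, b = b, sizes = sizes), class = "net_params")
  })
}

# Forward pass; returns activations per layer (A[[1]] = input).
fcnn_forward <- function(params, X) {
  L <- length(params$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% params$W[[l]], 2L, params$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) tanh(Z) else Z
  }
  A
}

#' Predict from a trained network
#'
#' @param object a `"net_params"` or `"fcnn_lm"` object.
#' @param newdata numeric matrix of inputs on the trained scale (for
#'   `"fcnn_lm"`, raw inputs -- the stored min-max scaler is applied).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.net_params <- function(object, newdata, ...) {
  A <- fcnn_forward(object, as.matrix(newdata))
  as.numeric(A[[length(A)]])
}

params_to_vec <- function(params) {
  unlist(c(lapply(params$W, as.numeric), params$b), use.names = FALSE)
}

vec_to_params <- function(v, params) {
  pos <- 0L
  for (l in seq_along(params$W)) {
    n <- length(params$W[[l]])
    params$W[[l]][] <- v[pos + seq_len(n)]; pos <- pos + n
  }
  for (l in seq_along(params$b)) {
    n <- length(params$b[[l]])
    params$b[[l]] <- v[pos + seq_len(n)]; pos <- pos + n
  }
  params
}

# Jacobian of predictions w.r.t. all parameters, n x p, by reverse-mode
# accumulation vectorized over samples (single-output network).
fcnn_jacobian <- function(params, A) {
  L <- length(params$W)
  n <- nrow(A[[1L]])
  # D[[l]]: n x width(l) sensitivities d yhat / d z_l
  D <- vector("list", L)
  D[[L]] <- matrix(1, n, 1L)
  for (l in rev(seq_len(L - 1L))) {
    D[[l]] <- (D[[l + 1L]] %*% t(params$W[[l + 1L]])) * (1 - A[[l + 1L]]^2)
  }
  Jw <- vector("list", L)
  for (l in seq_len(L)) {
    p_in <- ncol(A[[l]]); p_out <- ncol(D[[l]])
    # column (i, k) of the block is A[, i] * D[, k], column-major in W
    Jw[[l]] <- A[[l]][, rep(seq_len(p_in), times = p_out), drop = FALSE] *
      D[[l]][, rep(seq_len(p_out), each = p_in), drop = FALSE]
  }
  do.call(cbind, c(Jw, D))
}

#' Train the network by Levenberg-Marquardt
#'
#' Damped Gauss-Newton on the residual sum of squares: each epoch solves
#' `(J'J + mu I) delta = J'e` (in dual `n x n` form when parameters
#' outnumber samples), accepts the step when the training loss improves
#' (`mu` x 0.1) and otherwise raises `mu` (x 10) and retries.  Training
#' stops at `max_epochs`, when `mu` exceeds `mu_max`, or when the error on
#' an internal validation split (fraction `val_frac` of the training rows)
#' has not improved for `patience` consecutive epochs; the parameters with
#' the best validation error are returned.
#'
#' @param X numeric matrix of inputs, ideally scaled to [-1, 1].
#' @param y numeric target vector (ages in years).
#' @param hidden hidden-layer widths.
#' @param max_epochs maximum LM epochs.
#' @param mu0,mu_max initial and maximal damping.
#' @param val_frac fraction of rows held out for early stopping (0 disables).
#' @param patience epochs of non-improvement tolerated.
#' @param n_starts random restarts; the same validation split is shared and
#'   the restart with the lowest validation error wins (training error when
#'   `val_frac = 0`).  Restarting tames the run-to-run variance of
#'   Levenberg-Marquardt on small over-parameterized nets.
#' @param seed integer seed (weight init and validation split).
#' @return A `"net_params"` object with attributes `epochs`, `train_mse`,
#'   `val_mse`.
#' @export
train_lm <- function(X, y, hidden = c(10L, 10L, 10L), max_epochs = 100L,
                     mu0 = 1e-3, mu_max = 1e10, val_frac = 0.15,
                     patience = 10L, n_starts = 3L, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), n_starts >= 1L)
  if (nrow(X) < 20L && max_epochs > 0L) stop("need at least 20 samples")
  if (max_epochs <= 0L) {
    params <- fcnn_init(ncol(X), hidden, seed = seed)
    attr(params, "epochs") <- 0L
    return(params)
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    cand <- train_lm_once(X, y, hidden, max_epochs, mu0, mu_max, val_frac,
                          patience, init_seed = seed + 7919L * (s - 1L),
                          split_seed = seed)
    score <- attr(cand, "val_mse")
    if (is.na(score)) score <- attr(cand, "train_mse")
    if (is.null(best) || score < best_score) {
      best <- cand; best_score <- score
    }
  }
  best
}

train_lm_once <- function(X, y, hidden, max_epochs, mu0, mu_max, val_frac,
                          patience, init_seed, split_seed) {
  params <- fcnn_init(ncol(X), hidden, seed = init_seed)
  n <- nrow(X)
  idx_val <- integer(0)
  if (val_frac > 0 && n >= 20L) {
    n_val <- max(1L, round(val_frac * n))
    idx_val <- withr_seed(split_seed + 1L, sample.int(n, n_val))
  }
  idx_tr <- setdiff(seq_len(n), idx_val)
  Xtr <- X[idx_tr, , drop = FALSE]; ytr <- y[idx_tr]
  Xval <- X[idx_val, , drop = FALSE]; yval <- y[idx_val]
  mu <- mu0
  theta <- params_to_vec(params)
  A <- fcnn_forward(params, Xtr)
  e <- ytr - as.numeric(A[[length(A)]])
  loss <- mean(e^2)
  best_val <- Inf; best_theta <- theta; bad <- 0L; epochs_run <- 0L
  for (epoch in seq_len(max_epochs)) {
    J <- fcnn_jacobian(params, A)     # d yhat / d theta
    p <- ncol(J); ntr <- nrow(J)
    Jte <- crossprod(J, e)
    improved <- FALSE
    while (mu <= mu_max) {
      delta <- tryCatch({
        if (p <= ntr) {
          solve(crossprod(J) + diag(mu, p), Jte)
        } else {  # dual form: J'(J J' + mu I)^-1 e
          crossprod(J, solve(tcrossprod(J) + diag(mu, ntr), e))
        }
      }, error = function(err) NULL)
      if (!is.null(delta)) {
        theta_new <- theta + as.numeric(delta)
        cand <- vec_to_params(theta_new, params)
        A_new <- fcnn_forward(cand, Xtr)
        e_new <- ytr - as.numeric(A_new[[length(A_new)]])
        if (!all(is.finite(e_new))) stop("non-finite loss during training")
        loss_new <- mean(e_new^2)
        if (loss_new < loss) {
          theta <- theta_new; params <- cand; A <- A_new; e <- e_new
          loss <- loss_new
          mu <- max(mu * 0.1, 1e-20)
          improved <- TRUE
          break
        }
      }
      mu <- mu * 10
    }
    epochs_run <- epoch
    if (length(idx_val)) {
      val_mse <- mean((yval - predict.net_params(params, Xval))^2)
      if (val_mse < best_val - 1e-12) {
        best_val <- val_mse; best_theta <- theta; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    } else {
      best_theta <- theta
    }
    if (!improved || mu > mu_max) break
  }
  params <- vec_to_params(best_theta, params)
  attr(params, "epochs") <- epochs_run
  attr(params, "train_mse") <- loss
  attr(params, "val_mse") <- if (length(idx_val)) best_val else NA_real_
  params
}

#' @export
print.net_params <- function(x, ...) {
  cat(sprintf("Fully connected net %s, %d parameters%s\n",
              paste(x$sizes, collapse = "-"),
              length(params_to_vec(x)),
              if (!is.null(attr(x, "epochs")))
                sprintf(", trained %d epochs", attr(x, "epochs")) else ""))
  invisible(x)
}
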