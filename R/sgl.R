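#' Correlation-based group weights for the sparse group lasso
#'
#' The weight of group `j` is the sum of absolute Pearson correlations
#' between the target vector and each regressor column in the group,
#' reflecting the overall similarity between the target feature and that
#' feature group.  Zero-variance columns contribute a correlation of 0.
#'
#' @param x target vector (length d >= 3).
#' @param A regressor matrix, d x p.
#' @param groups integer/character vector of length p assigning each column
#'   to a group.
#' @return Named numeric vector of per-group weights, in the order the
#'   groups first appear.
#' @export
sgl_group_weights <- function(x, A, groups) {
  stopifnot(is.matrix(A), length(x) == nrow(A), length(groups) == ncol(A))
  if (nrow(A) < 3L) stop("need at least 3 observations")
  sx <- stats::sd(x)
  r <- apply(A, 2L, function(col) {
    s <- stats::sd(col)
    if (s == 0 || sx == 0) 0 else stats::cor(x, col)
  })
  z <- tapply(abs(r), factor(groups, levels = unique(groups)), sum)
  out <- as.numeric(z)
  names(out) <- names(z)
  out
}

sgl_objective <- function(w, x, A, lambda1, lambda2, groups, z) {
  gl <- unique(groups)
  pen2 <- 0
  for (j in seq_along(gl))
    pen2 <- pen2 + z[j] * sqrt(sum(w[groups == gl[j]]^2))
  0.5 * sum((x - A %*% w)^2) + lambda1 * sum(abs(w)) + lambda2 * pen2
}

# Proximal operator of t*(lambda1 ||.||_1 + lambda2 sum z_j ||._Gj||_2):
# elementwise soft threshold, then per-group norm shrinkage.
sgl_prox <- function(v, t, lambda1, lambda2, groups, gl, z) {
  u <- sign(v) * pmax(abs(v) - t * lambda1, 0)
  for (j in seq_along(gl)) {
    idx <- groups == gl[j]
    nrm <- sqrt(sum(u[idx]^2))
    shrink <- t * lambda2 * z[j]
    u[idx] <- if (nrm <= shrink) 0 else u[idx] * (1 - shrink / nrm)
  }
  u
}

#' Solve one sparse-group-lasso regression
#'
#' Minimizes `0.5 ||x - A w||^2 + lambda1 ||w||_1 +
#' lambda2 sum_j z_j ||w_Gj||_2` by accelerated proximal gradient (FISTA)
#' with step `1/L` (`L` = squared spectral norm of `A`), monotone restart on
#' objective increase, and convergence on relative objective change below
#' `tol`.  The proximal map of the composite penalty is the elementwise soft
#' threshold followed by per-group norm shrinkage (the Moreau-Yosida
#' regularization of the sparse group lasso).
#'
#' @param x target vector.
#' @param A regressor matrix d x p.
#' @param groups group assignment of the p columns.
#' @param lambda1 L1 penalty (>= 0).
#' @param lambda2 group penalty (>= 0).
#' @param z per-group weights; computed by [sgl_group_weights()] when `NULL`.
#' @param tol relative objective-change convergence threshold.
#' @param max_iter maximum iterations.
#' @return Numeric coefficient vector of length p with attributes
#'   `"objective"`, `"iterations"`, `"kkt"` (max KKT residual) and
#'   `"converged"`.
#' @export
solve_sgl <- function(x, A, groups, lambda1, lambda2, z = NULL,
                      tol = 1e-8, max_iter = 10000L) {
  stopifnot(is.matrix(A), length(x) == nrow(A), length(groups) == ncol(A),
            lambda1 >= 0, lambda2 >= 0, all(is.finite(A)), all(is.finite(x)))
  gl <- unique(groups)
  if (is.null(z)) z <- sgl_group_weights(x, A, groups)
  stopifnot(length(z) == length(gl), all(z >= 0))
  p <- ncol(A)
  L <- max(svd(A, nu = 0, nv = 0)$d)^2
  if (L <= 0) return(structure(numeric(p), objective = 0.5 * sum(x^2),
                               iterations = 0L, kkt = 0, converged = TRUE))
  t_step <- 1 / L
  w <- numeric(p); y <- w; th <- 1
  obj <- sgl_objective(w, x, A, lambda1, lambda2, groups, z)
  AtA <- crossprod(A); Atx <- crossprod(A, x)
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    grad <- AtA %*% y - Atx
    w_new <- sgl_prox(y - t_step * grad, t_step, lambda1, lambda2, groups, gl, z)
    obj_new <- sgl_objective(w_new, x, A, lambda1, lambda2, groups, z)
    if (obj_new > obj) {            # restart momentum; plain proximal step
      th <- 1
      y <- w
      grad <- AtA %*% w - Atx
      w_new <- sgl_prox(w - t_step * grad, t_step, lambda1, lambda2, groups, gl, z)
      obj_new <- sgl_objective(w_new, x, A, lambda1, lambda2, groups, z)
    }
    th_new <- (1 + sqrt(1 + 4 * th^2)) / 2
    y <- w_new + ((th - 1) / th_new) * (w_new - w)
    rel <- abs(obj - obj_new) / max(1, abs(obj))
    w <- as.numeric(w_new); obj <- obj_new; th <- th_new
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    kkt <- sgl_kkt_residual(w, x, A, groups, gl, z, lambda1, lambda2)
    stop(sprintf(paste0("sparse group lasso did not converge in %d iterations",
                        " (KKT residual %.3g); last objective %.6g"),
                 max_iter, kkt, obj))
  }
  # plain proximal-gradient polish: the objective-change test stalls at the
  # floating-point floor around sqrt(eps) parameter accuracy, but gradient
  # steps remain informative well below it
  kkt_floor <- 1e-10 * max(1, max(abs(Atx)))
  for (it2 in seq_len(500L)) {
    kkt <- sgl_kkt_residual(w, x, A, groups, gl, z, lambda1, lambda2)
    if (kkt < kkt_floor) break
    w_new <- sgl_prox(w - t_step * as.numeric(AtA %*% w - Atx), t_step,
                      lambda1, lambda2, groups, gl, z)
    if (max(abs(w_new - w)) == 0) break
    w <- as.numeric(w_new)
  }
  obj <- sgl_objective(w, x, A, lambda1, lambda2, groups, z)
  kkt <- sgl_kkt_residual(w, x, A, groups, gl, z, lambda1, lambda2)
  structure(w, objective = obj, iterations = it, kkt = kkt, converged = TRUE)
}

# Max violation of the subgradient optimality conditions.
sgl_kkt_residual <- function(w, x, A, groups, gl, z, lambda1, lambda2) {
  g <- as.numeric(crossprod(A, A %*% w - x))
  viol <- 0
  for (j in seq_along(gl)) {
    idx <- which(groups == gl[j])
    wj <- w[idx]; gj <- g[idx]
    if (sqrt(sum(wj^2)) > 0) {
      gr <- gj + lambda2 * z[j] * wj / sqrt(sum(wj^2))
      for (i in seq_along(idx)) {
        viol <- max(viol, if (wj[i] != 0)
          abs(gr[i] + lambda1 * sign(wj[i]))
          else max(0, abs(gr[i]) - lambda1))
      }
    } else {
      # group at zero: distance of -g_j to the product subdifferential
      resid_after_l1 <- pmax(abs(gj) - lambda1, 0)
      viol <- max(viol, max(0, sqrt(sum(resid_after_l1^2)) - lambda2 * z[j]))
    }
  }
  viol
}

#' Candidate penalty grid
#'
#' The standard search grid: `lambda1` on the dyadic scale `2^-1 ... 2^-10`,
#' `lambda2` on the natural scale `0, 0.1, ..., 0.9` (10 x 10 pairs).
#'
#' @return List with `lambda1` and `lambda2` vectors.
#' @export
lambda_grid <- function() {
  list(lambda1 = 2^-(1:10), lambda2 = seq(0, 0.9, by = 0.1))
}

#' Build a subject's inter-feature dependency (ODC) matrix
#'
#' Each of the 13 features' 18-electrode profiles is regressed on the other
#' 12 by sparse group lasso; the 13 coefficient rows form the asymmetric
#' 13 x 12 dependency matrix.  Feature columns (and the target) are
#' z-scored across electrodes first -- the features mix units (Hz,
#' log-power, ratios), and on a common scale the penalty weights act
#' comparably across features.  The target's group keeps its remaining
#' members among the regressor groups.
#'
#' @param osf_subject electrode x feature matrix (18 x 13).
#' @param lambda1,lambda2 penalty parameters.
#' @param groups feature-group labels (defaults to [osf_feature_groups()]).
#' @param tol,max_iter solver controls, see [solve_sgl()].
#' @return An `m x (m - 1)` matrix of class `"odc_matrix"`; row `i` holds
#'   the coefficients of the regression with feature `i` as target, columns
#'   indexed by the remaining features in canonical order.
#' @export
build_odc <- function(osf_subject, lambda1, lambda2,
                      groups = NULL, tol = 1e-8, max_iter = 10000L) {
  stopifnot(is.matrix(osf_subject))
  m <- ncol(osf_subject)
  if (is.null(groups)) {
    if (m != 13L) stop("default groups assume the 13 canonical features")
    groups <- unname(osf_feature_groups())
  }
  stopifnot(length(groups) == m)
  X <- apply(osf_subject, 2L, function(col) {
    s <- stats::sd(col)
    if (s == 0) {
      warning("zero-variance feature column z-scored to zeros")
      rep(0, length(col))
    } else (col - mean(col)) / s
  })
  W <- matrix(0, m, m - 1L)
  fn <- colnames(osf_subject)
  for (i in seq_len(m)) {
    A <- X[, -i, drop = FALSE]
    W[i, ] <- solve_sgl(X[, i], A, groups[-i], lambda1, lambda2,
                        tol = tol, max_iter = max_iter)
  }
  dimnames(W) <- if (!is.null(fn)) list(target = fn, regressor = NULL) else NULL
  structure(W, class = "odc_matrix", lambda1 = lambda1, lambda2 = lambda2,
            feature_names = fn, groups = groups)
}

#' ODC matrices for a whole cohort
#'
#' @param osf an [build_osf_table()] result.
#' @inheritParams build_odc
#' @return Array subjects x m x (m - 1) of class `"odc_cohort"`.
#' @export
odc_cohort <- function(osf, lambda1, lambda2, tol = 1e-8, max_iter = 10000L) {
  stopifnot(inherits(osf, "osf_table"))
  d <- dim(osf)
  out <- array(NA_real_, dim = c(d[1L], d[3L], d[3L] - 1L),
               dimnames = list(dimnames(osf)[[1L]], dimnames(osf)[[3L]], NULL))
  for (s in seq_len(d[1L]))
    out[s, , ] <- build_odc(osf[s, , ], lambda1, lambda2,
                            tol = tol, max_iter = max_iter)
  structure(out, class = "odc_cohort", lambda1 = lambda1, lambda2 = lambda2)
}

#' Grid search for the sparse-group-lasso penalties
#'
#' Evaluates a downstream cross-validation pipeline at every `(lambda1,
#' lambda2)` pair of the grid and returns the pair with the least MAE; ties
#' go to the smaller `lambda1`, then the smaller `lambda2`.
#'
#' @param osf an [build_osf_table()] result.
#' @param ages subject ages aligned with the table.
#' @param grid a [lambda_grid()]-style list.
#' @param evaluator `function(osf, ages, lambda1, lambda2) -> MAE`; defaults
#'   to the fused-input 10-fold CV pipeline (see [neoba_fit()]).
#' @param verbose print progress.
#' @return List with `lambda1`, `lambda2`, and the full `mae` matrix
#'   (rows lambda1, columns lambda2).
#' @export
sgl_grid_search <- function(osf, ages, grid = lambda_grid(),
                            evaluator = NULL, verbose = FALSE) {
  if (is.null(evaluator)) {
    evaluator <- function(osf, ages, l1, l2) {
      odc <- odc_cohort(osf, l1, l2)
      X <- assemble_input(osf, odc, mode = "fused")
      cv <- kfold_cv(X$matrix, ages, k = 10L, seed = 1L)
      cv$pooled["mae"]
    }
  }
  mae <- matrix(NA_real_, length(grid$lambda1), length(grid$lambda2),
                dimnames = list(paste0("2^-", round(-log2(grid$lambda1))),
                                format(grid$lambda2)))
  for (i in seq_along(grid$lambda1)) {
    for (j in seq_along(grid$lambda2)) {
      mae[i, j] <- evaluator(osf, ages, grid$lambda1[i], grid$lambda2[j])
      if (verbose)
        message(sprintf("lambda1=%g lambda2=%g MAE=%.3f",
                        grid$lambda1[i], grid$lambda2[j], mae[i, j]))
    }
  }
  best <- which(mae == min(mae), arr.ind = TRUE)
  # ties: smaller lambda1 means larger exponent index? lambda1 decreasing in
  # index, so smaller lambda1 = larger i; spec orders candidates by value.
  best <- best[order(grid$lambda1[best[, 1L]], grid$lambda2[best[, 2L]]), ,
               drop = FALSE][1L, ]
  list(lambda1 = grid$lambda1[best[1L]], lambda2 = grid$lambda2[best[2L]],
       mae = mae)
}
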