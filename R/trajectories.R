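#' Average a feature over electrodes
#'
#' @param osf an [build_osf_table()] result.
#' @param feature one of [osf_feature_names()].
#' @return Per-subject numeric vector.
#' @export
electrode_average <- function(osf, feature) {
  stopifnot(inherits(osf, "osf_table"))
  fn <- dimnames(osf)[[3L]]
  if (!feature %in% fn) stop(sprintf("unknown feature '%s'", feature))
  rowMeans(osf[, , which(fn == feature), drop = TRUE])
}

# Pinball (check) loss.
pinball_loss <- function(r, tau) mean(r * (tau - (r < 0)))

# Penalized B-spline quantile regression via asymmetric-weight IRLS:
# minimize sum rho_tau(y - B theta) + lambda ||D2 theta||^2.
fit_pspline_quantile <- function(B, y, tau, lambda, n_iter = 60L,
                                 delta = 1e-6) {
  p <- ncol(B)
  D <- diff(diag(p), differences = 2L)
  P <- lambda * crossprod(D)
  theta <- qr.solve(crossprod(B) + P + diag(1e-10, p), crossprod(B, y))
  for (it in seq_len(n_iter)) {
    r <- y - as.numeric(B %*% theta)
    w <- ifelse(r > 0, tau, 1 - tau) / (abs(r) + delta)
    BW <- B * w
    theta_new <- tryCatch(
      qr.solve(crossprod(BW, B) + P + diag(1e-10, p), crossprod(BW, y)),
      error = function(e) theta)
    if (max(abs(theta_new - theta)) < 1e-8 * (1 + max(abs(theta)))) {
      theta <- theta_new; break
    }
    theta <- theta_new
  }
  as.numeric(theta)
}

#' Lifespan quantile trajectory of a feature
#'
#' Fits penalized cubic B-spline quantile curves (pinball loss, second-
#' difference penalty) of a feature against log(age), one curve per
#' requested quantile level, then applies monotone rearrangement across
#' levels at every evaluation age so the quantile curves never cross.
#' The smoothing parameter is chosen by 5-fold cross-validation on the
#' median-level pinball loss unless given.
#'
#' @param ages positive ages (years), n >= 30 with >= 10 unique values.
#' @param values feature values, same length.
#' @param levels quantile levels (default 0.25, 0.5, 0.75).
#' @param smoothing penalty weight lambda; `NULL` selects by CV over
#'   `10^(-2..4)`.
#' @param df basis dimension (default 8).
#' @param n_grid evaluation grid size over the observed age range.
#' @return An object of class `"osf_trajectory"`: `age_grid`, `quantiles`
#'   (grid x levels matrix), `levels`, `smoothing`, plus the basis spec for
#'   [predict.osf_trajectory()].
#' @export
fit_trajectory <- function(ages, values, levels = c(0.25, 0.5, 0.75),
                           smoothing = NULL, df = 8L, n_grid = 101L) {
  stopifnot(length(ages) == length(values), all(ages > 0),
            all(levels > 0 & levels < 1))
  if (length(ages) < 30L) stop("need at least 30 observations")
  if (length(unique(ages)) < 10L) stop("need at least 10 unique ages")
  lx <- log(ages)
  bknots <- range(lx)
  # true P-spline basis: cubic B-splines on uniformly spaced knots extended
  # past both boundaries, so the second-difference coefficient penalty
  # vanishes exactly on linear functions and smoothing shrinks curvature
  # without biasing trends (repeated boundary knots would not have this
  # property)
  step <- diff(bknots) / (df - 3L)
  knots_all <- seq(bknots[1L] - 3 * step, bknots[2L] + 3 * step, by = step)
  basis <- function(x) splines::splineDesign(knots_all, x, ord = 4L,
                                             outer.ok = TRUE)
  B <- basis(lx)
  if (is.null(smoothing)) {
    lams <- 10^seq(-2, 4, by = 1)
    fold <- withr_seed(7L, sample(rep(1:5, length.out = length(lx))))
    cv_loss <- vapply(lams, function(lam) {
      loss <- 0
      for (f in 1:5) {
        te <- fold == f
        th <- fit_pspline_quantile(B[!te, , drop = FALSE], values[!te],
                                   0.5, lam)
        loss <- loss + pinball_loss(values[te] - as.numeric(
          B[te, , drop = FALSE] %*% th), 0.5)
      }
      loss
    }, numeric(1))
    smoothing <- lams[which.min(cv_loss)]
  }
  theta <- lapply(levels, function(tau)
    fit_pspline_quantile(B, values, tau, smoothing))
  age_grid <- exp(seq(bknots[1L], bknots[2L], length.out = n_grid))
  Bg <- basis(log(age_grid))
  Q <- vapply(theta, function(th) as.numeric(Bg %*% th), numeric(n_grid))
  Q <- rearrange_rows(Q)                  # monotone rearrangement
  colnames(Q) <- paste0("q", levels * 100)
  structure(list(age_grid = age_grid, quantiles = Q, levels = levels,
                 smoothing = smoothing, theta = theta, knots = knots_all,
                 bknots = bknots, age_range = range(ages)),
            class = "osf_trajectory")
}

#' @export
print.osf_trajectory <- function(x, ...) {
  cat(sprintf("Quantile trajectory: levels %s, smoothing %g, ages %.3g-%.3g y\n",
              paste(x$levels, collapse = "/"), x$smoothing,
              x$age_range[1L], x$age_range[2L]))
  invisible(x)
}

#' @export
#' @rdname fit_trajectory
#' @param object an `"osf_trajectory"`.
#' @param newages ages at which to evaluate (clamped to the fitted range).
#' @param ... unused.
predict.osf_trajectory <- function(object, newages, ...) {
  newages <- pmin(pmax(newages, object$age_range[1L]), object$age_range[2L])
  Bg <- splines::splineDesign(object$knots, log(newages), ord = 4L,
                              outer.ok = TRUE)
  Q <- vapply(object$theta, function(th) as.numeric(Bg %*% th),
              numeric(length(newages)))
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = length(newages))
  Q <- rearrange_rows(Q)
  colnames(Q) <- paste0("q", object$levels * 100)
  Q
}

# sort each row (no-op for a single quantile level)
rearrange_rows <- function(Q) {
  if (is.null(dim(Q))) Q <- matrix(Q, ncol = 1L)
  if (ncol(Q) > 1L) Q <- t(apply(Q, 1L, sort))
  Q
}

#' @export
plot.osf_trajectory <- function(x, y, ...) {
  matplot(x$age_grid, x$quantiles, type = "l", lty = c(2, 1, 2),
          col = "steelblue", log = "x", xlab = "Age (years, log scale)",
          ylab = "Feature value", ...)
  invisible(x)
}
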