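# Shared fixtures and independent oracles for the test suite.

default_freqs <- function() frequency_grid()$freqs

# Tiny deterministic power-spectra object (linear scale).
tiny_psd <- function(n_subj = 2L, n_ch = 2L, n_f = 3L, scale = "linear") {
  grid <- frequency_grid(2, 1, n_f)
  vals <- array(seq_len(n_subj * n_ch * n_f) / 10 + 1,
                dim = c(n_subj, n_ch, n_f))
  power_spectra(vals, grid, paste0("C", seq_len(n_ch)), scale = scale)
}

# Independent sparse-group-lasso oracle: cyclic coordinate minimization with
# exact 1-D solutions (closed form when the rest of the group is zero,
# root-finding otherwise).  Deliberately shares no code with solve_sgl().
sgl_oracle <- function(x, A, groups, lambda1, lambda2, z,
                       n_sweeps = 5000L, tol = 1e-12) {
  p <- ncol(A)
  gl <- unique(groups)
  w <- numeric(p)
  r <- x - A %*% w
  a2 <- colSums(A^2)
  obj_prev <- Inf
  for (sweep in seq_len(n_sweeps)) {
    for (k in seq_len(p)) {
      j <- match(groups[k], gl)
      idx <- which(groups == groups[k])
      s2 <- sum(w[idx]^2) - w[k]^2
      rk <- as.numeric(r) + A[, k] * w[k]      # residual excluding coord k
      rho <- sum(A[, k] * rk)
      lam2 <- lambda2 * z[j]
      w_new <- if (s2 <= 1e-300) {
        # whole group at zero except this coordinate: combined L1 threshold
        th <- lambda1 + lam2
        if (abs(rho) <= th) 0 else (rho - sign(rho) * th) / a2[k]
      } else {
        # subgradient check at 0, else smooth scalar root on the sign branch
        if (abs(rho) <= lambda1) 0 else {
          sgn <- sign(rho)
          g <- function(v) a2[k] * v - rho + lambda1 * sgn +
            lam2 * v / sqrt(v^2 + s2)
          hi <- abs(rho) / a2[k] + 1
          root <- stats::uniroot(g, c(0, sgn * hi)[order(c(0, sgn * hi))],
                                 tol = 1e-14)$root
          root
        }
      }
      if (w_new != w[k]) {
        r <- r - A[, k] * (w_new - w[k])
        w[k] <- w_new
      }
    }
    obj <- 0.5 * sum(r^2) + lambda1 * sum(abs(w)) +
      sum(vapply(seq_along(gl), function(j)
        lambda2 * z[j] * sqrt(sum(w[groups == gl[j]]^2)), numeric(1)))
    if (abs(obj_prev - obj) < tol * max(1, abs(obj))) break
    obj_prev <- obj
  }
  list(w = w, objective = obj)
}

# Random SGL problem in the standard 18 x 12 / 4-group configuration.
random_sgl_problem <- function(seed) {
  set.seed(seed)
  A <- matrix(rnorm(18 * 12), 18)
  x <- rnorm(18)
  groups <- rep(c("AP", "PP", "PR", "RP"), c(1L, 3L, 4L, 4L))
  z <- sgl_group_weights(x, A, groups)
  list(x = x, A = A, groups = groups, z = z)
}

# Small trained network on synthetic features, reused by LRP tests.
trained_toy_net <- function(n = 60L, p = 12L, seed = 5L) {
  set.seed(seed)
  X <- matrix(runif(n * p, -1, 1), n)
  y <- 30 + 10 * X[, 1] - 5 * X[, 2] + rnorm(n, 0, 0.5)
  net <- train_lm(X, y, max_epochs = 30L, seed = seed, n_starts = 1L)
  list(net = net, X = X, y = y)
}
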