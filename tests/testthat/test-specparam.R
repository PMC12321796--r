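test_that("fixed-mode aperiodic fit is exact on pure power laws", {
  freqs <- default_freqs()
  fit <- fit_aperiodic(1.0 - 1.5 * log(freqs), freqs)
  expect_equal(fit$b, 1.0, tolerance = 1e-6)
  expect_equal(fit$chi, 1.5, tolerance = 1e-6)
  # flat zero spectrum
  flat <- fit_aperiodic(rep(0, 47), freqs)
  expect_equal(flat$b, 0, tolerance = 1e-10)
  expect_equal(flat$chi, 0, tolerance = 1e-10)
  expect_error(fit_aperiodic(1:4, freqs[1:4]), "at least 5")
})

test_that("robust pass excludes peak bins from the aperiodic fit", {
  freqs <- default_freqs()
  y <- 2 - 1 * log(freqs) + 0.6 * exp(-(freqs - 10)^2 / 2)
  fit <- fit_aperiodic(y, freqs)
  expect_lt(abs(fit$b - 2), 0.05)
  expect_lt(abs(fit$chi - 1), 0.05)
  expect_lt(fit$n_used, 47L)
})

test_that("monotonicity: larger exponent lowers the aperiodic curve above 1 Hz", {
  freqs <- seq(1.5, 19, by = 0.5)
  l1 <- 1 - 0.8 * log(freqs)
  l2 <- 1 - 1.6 * log(freqs)
  expect_true(all(l2 < l1))
  # the model value helper agrees
  expect_equal(neoba:::aperiodic_values(freqs, 1, 0.8), l1)
})

test_that("peak extraction finds and orders Gaussian bumps", {
  freqs <- default_freqs()
  expect_length(extract_peaks(rep(0, 47), freqs), 0L)
  set.seed(12)
  resid <- 0.5 * exp(-(freqs - 10)^2 / (2 * 1.2^2)) + rnorm(47, 0, 0.01)
  pks <- extract_peaks(resid, freqs)
  expect_length(pks, 1L)
  expect_lt(abs(pks[[1]]$c - 10), 0.2)
  # two separated peaks in descending-power order
  resid2 <- 0.6 * exp(-(freqs - 10)^2 / 2) + 0.4 * exp(-(freqs - 5)^2 / 2)
  pks2 <- extract_peaks(resid2, freqs)
  expect_length(pks2, 2L)
  expect_gt(pks2[[1]]$p, pks2[[2]]$p)
  expect_lt(abs(pks2[[1]]$c - 10), 0.2)
  expect_lt(abs(pks2[[2]]$c - 5), 0.2)
})

test_that("full decomposition recovers noiseless parameters to 1e-3", {
  freqs <- default_freqs()
  y <- 1.8 - 1.2 * log(freqs) + 0.6 * exp(-(freqs - 10)^2 / (2 * 1.2^2))
  m <- fit_spectrum(y, freqs)
  pk <- select_dominant_peak(m)
  expect_lt(abs(m$aperiodic$b - 1.8), 1e-3)
  expect_lt(abs(m$aperiodic$chi - 1.2), 1e-3)
  expect_lt(abs(pk$c - 10), 1e-3)
  expect_lt(abs(pk$p - 0.6), 1e-3)
  expect_lt(abs(pk$w - 1.2), 1e-3)
  expect_gt(m$r2, 0.999)
  # aperiodic-only spectrum: no peaks, r2 ~ 1
  m0 <- fit_spectrum(1 - log(freqs), freqs)
  expect_length(m0$peaks, 0L)
  expect_gte(m0$r2, 0.999)
})

test_that("white-noise residuals never exceed the peak budget or height floor", {
  freqs <- default_freqs()
  set.seed(77)
  cfg <- spec_config()
  for (i in 1:5) {
    y <- 1 - log(freqs) + rnorm(47, 0, 0.5)
    m <- fit_spectrum(y, freqs, cfg)
    expect_lte(length(m$peaks), cfg$max_peaks)
    for (p in m$peaks) {
      expect_gte(p$p, cfg$min_height)
      expect_gte(p$w, cfg$bw_lim[1L])
      expect_lte(p$w, cfg$bw_lim[2L])
    }
  }
})

test_that("full-model fit never explains less variance than aperiodic alone", {
  freqs <- default_freqs()
  set.seed(31)
  for (i in 1:5) {
    y <- 1.5 - runif(1, 0.8, 2) * log(freqs) +
      0.5 * exp(-(freqs - runif(1, 6, 12))^2 / 2) + rnorm(47, 0, 0.05)
    m <- fit_spectrum(y, freqs)
    ap_fit <- fit_aperiodic(y, freqs)
    ap_only <- neoba:::aperiodic_values(freqs, ap_fit$b, ap_fit$chi)
    r2_ap <- 1 - sum((y - ap_only)^2) / sum((y - mean(y))^2)
    expect_gte(m$r2, r2_ap - 1e-9)
  }
})

test_that("dominant-peak selection uses max power with low-frequency ties", {
  model <- structure(list(
    aperiodic = structure(list(b = 1, k = 0, chi = 1, mode = "fixed",
                               fit_error = 0, n_used = 47L),
                          class = "aperiodic_fit"),
    peaks = list(list(c = 10, p = 0.5, w = 1), list(c = 6, p = 0.3, w = 1)),
    r2 = 1, fitted = NULL, freqs = NULL), class = "spectral_model")
  expect_equal(select_dominant_peak(model)$c, 10)
  model$peaks <- list(list(c = 11, p = 0.4, w = 1), list(c = 8, p = 0.4, w = 1))
  expect_equal(select_dominant_peak(model)$c, 8)
  model$peaks <- list()
  expect_null(select_dominant_peak(model))
})

test_that("decomposition matches a grid+polish oracle on noiseless spectra", {
  freqs <- default_freqs()
  set.seed(101)
  n_cfg <- 20L
  for (i in seq_len(n_cfg)) {
    b <- runif(1, 0.5, 2.5); chi <- runif(1, 0.5, 2.2)
    n_pk <- sample(0:2, 1)
    cs <- if (n_pk == 2) c(6, 11) + runif(2, -0.5, 0.5)
          else if (n_pk == 1) runif(1, 6, 12) else numeric(0)
    ps <- runif(n_pk, 0.35, 0.8); ws <- runif(n_pk, 1, 1.8)
    y <- b - chi * log(freqs)
    for (j in seq_len(n_pk)) y <- y + ps[j] * exp(-(freqs - cs[j])^2 / (2 * ws[j]^2))
    m <- fit_spectrum(y, freqs)
    # oracle: joint least squares from a coarse grid of aperiodic starts,
    # peak count known
    oracle_obj <- function(par) {
      model <- par[1] - par[2] * log(freqs)
      for (j in seq_len(n_pk)) {
        k <- 2 + 3 * (j - 1)
        model <- model + par[k + 1] * exp(-(freqs - par[k + 3])^2 / (2 * par[k + 2]^2))
      }
      sum((y - model)^2)
    }
    best <- NULL
    for (b0 in seq(0, 3, by = 1.5)) for (chi0 in seq(0.5, 2.5, by = 1)) {
      par0 <- c(b0, chi0)
      for (j in seq_len(n_pk)) par0 <- c(par0, 0.5, 1.2, cs[j] + 0.3)
      op <- optim(par0, oracle_obj, method = "BFGS",
                  control = list(maxit = 2000, reltol = 1e-15))
      if (is.null(best) || op$value < best$value) best <- op
    }
    expect_lt(abs(m$aperiodic$b - best$par[1]), 1e-3)
    expect_lt(abs(m$aperiodic$chi - best$par[2]), 1e-3)
    if (n_pk > 0) expect_equal(length(m$peaks), n_pk)
  }
})
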