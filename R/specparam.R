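#' Settings for spectral decomposition
#'
#' Tunable parameters for [fit_spectrum()] and friends.  Defaults: fixed
#' aperiodic mode (no knee), at most 6 peaks, minimum detectable peak height
#' 0.05 log units, relative threshold 2 SD of the flattened residual, peak
#' bandwidth (Gaussian SD) limited to [0.5, 12] Hz, robust-fit percentile
#' 0.025 on the positive residual.
#'
#' @param mode `"fixed"` (knee pinned at 0) or `"knee"`.
#' @param max_peaks maximum number of Gaussian peaks.
#' @param min_height absolute peak-detection threshold (log-power units).
#' @param rel_thresh relative threshold in SD multiples of the residual.
#' @param bw_lim length-2 numeric, bandwidth limits in Hz.
#' @param ap_percentile percentile of the positive residual below which bins
#'   are kept for the second (robust) aperiodic pass.
#' @param max_iter maximum optimizer iterations per fit.
#' @return A list of class `"spec_config"`.
#' @export
spec_config <- function(mode = c("fixed", "knee"), max_peaks = 6L,
                        min_height = 0.05, rel_thresh = 2,
                        bw_lim = c(0.5, 12), ap_percentile = 0.025,
                        max_iter = 500L) {
  mode <- match.arg(mode)
  stopifnot(max_peaks >= 0, min_height >= 0, rel_thresh >= 0,
            length(bw_lim) == 2L, bw_lim[1L] > 0, bw_lim[2L] > bw_lim[1L],
            ap_percentile >= 0, ap_percentile <= 1)
  structure(list(mode = mode, max_peaks = as.integer(max_peaks),
                 min_height = min_height, rel_thresh = rel_thresh,
                 bw_lim = bw_lim, ap_percentile = ap_percentile,
                 max_iter = as.integer(max_iter)),
            class = "spec_config")
}

# Aperiodic model on the natural-log scale: L(F) = b - log(k + F^chi).
aperiodic_values <- function(freqs, b, chi, k = 0) b - log(k + freqs^chi)

# Plain (non-robust) aperiodic fit.  Fixed mode is linear in (b, chi):
# y = b - chi * log(F).  Knee mode polishes (b, k, chi) by bounded
# quasi-Newton from the fixed-mode solution.
fit_aperiodic_plain <- function(freqs, y, mode, max_iter = 500L) {
  lx <- log(freqs)
  fit <- stats::lm.fit(cbind(1, -lx), y)
  b <- fit$coefficients[[1L]]; chi <- fit$coefficients[[2L]]
  if (!is.finite(b) || !is.finite(chi)) stop("aperiodic fit failed to converge")
  if (chi < 0) {  # exponent constrained nonnegative; refit offset alone
    chi <- 0
    b <- mean(y)
  }
  k <- 0
  if (mode == "knee") {
    obj <- function(p) sum((y - aperiodic_values(freqs, p[1L], p[3L], p[2L]))^2)
    op <- stats::optim(c(b, 1e-3, max(chi, 1e-3)), obj, method = "L-BFGS-B",
                       lower = c(-Inf, 0, 0), upper = c(Inf, Inf, 10),
                       control = list(maxit = max_iter, factr = 1e4))
    b <- op$par[1L]; k <- op$par[2L]; chi <- op$par[3L]
  }
  list(b = unname(b), k = unname(k), chi = unname(chi))
}

#' Fit the aperiodic (1/f-like) component of a log power spectrum
#'
#' Two-pass robust fit of `L(F) = b - log(k + F^chi)` (natural log).  The
#' first pass fits all bins; bins whose positive residual exceeds the
#' configured percentile of the positively clipped residual are dropped
#' (flattening out oscillatory peaks) and the remaining bins are refit.
#' In `"fixed"` mode the knee `k` is pinned at 0 and the model is linear in
#' `(b, chi)` on a log-frequency axis.
#'
#' @param psd_log numeric vector of natural-log power values over `freqs`.
#' @param freqs positive frequencies (Hz), at least 5 bins.
#' @param mode `"fixed"` or `"knee"`.
#' @param config a [spec_config()].
#' @return An object of class `"aperiodic_fit"`: list with `b` (offset),
#'   `k` (knee), `chi` (exponent, >= 0), `fit_error` (mean absolute
#'   residual) and `n_used` (bins kept in the robust pass).
#' @examples
#' g <- frequency_grid()
#' fit <- fit_aperiodic(1 - 1.5 * log(g$freqs), g$freqs)
#' c(fit$b, fit$chi)  # ~ (1, 1.5)
#' @export
fit_aperiodic <- function(psd_log, freqs, mode = NULL, config = spec_config()) {
  if (is.null(mode)) mode <- config$mode
  mode <- match.arg(mode, c("fixed", "knee"))
  stopifnot(length(psd_log) == length(freqs), all(freqs > 0))
  if (length(freqs) < 5L) stop("need at least 5 frequency bins")
  if (!all(is.finite(psd_log))) stop("non-finite power values")
  p1 <- fit_aperiodic_plain(freqs, psd_log, mode, config$max_iter)
  resid <- psd_log - aperiodic_values(freqs, p1$b, p1$chi, p1$k)
  rpos <- pmax(resid, 0)
  thresh <- stats::quantile(rpos, config$ap_percentile, names = FALSE)
  keep <- rpos <= thresh
  if (sum(keep) >= 5L) {
    p2 <- fit_aperiodic_plain(freqs[keep], psd_log[keep], mode, config$max_iter)
  } else {
    p2 <- p1
    keep <- rep(TRUE, length(freqs))
  }
  fe <- mean(abs(psd_log - aperiodic_values(freqs, p2$b, p2$chi, p2$k)))
  structure(list(b = p2$b, k = p2$k, chi = p2$chi, mode = mode,
                 fit_error = fe, n_used = sum(keep)),
            class = "aperiodic_fit")
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("Aperiodic fit (%s): offset %.4g, exponent %.4g%s, MAE %.3g\n",
              x$mode, x$b, x$chi,
              if (x$mode == "knee") sprintf(", knee %.4g", x$k) else "",
              x$fit_error))
  invisible(x)
}

gaussian_peak <- function(freqs, c_n, p_n, w_n) {
  p_n * exp(-(freqs - c_n)^2 / (2 * w_n^2))
}

peaks_values <- function(freqs, peaks) {
  out <- numeric(length(freqs))
  for (p in peaks) out <- out + gaussian_peak(freqs, p$c, p$p, p$w)
  out
}

# SSE and analytic gradient for a sum of Gaussians (+ optional linear
# aperiodic part b - chi*log(F) when ap = TRUE, prepended to the parameters).
gauss_model_sse <- function(par, freqs, y, k, ap = FALSE) {
  off <- if (ap) 2L else 0L
  model <- if (ap) par[1L] - par[2L] * log(freqs) else numeric(length(freqs))
  for (i in seq_len(k)) {
    j <- off + 3L * (i - 1L)
    model <- model + gaussian_peak(freqs, par[j + 1L], par[j + 2L], par[j + 3L])
  }
  sum((y - model)^2)
}

gauss_model_grad <- function(par, freqs, y, k, ap = FALSE) {
  off <- if (ap) 2L else 0L
  model <- if (ap) par[1L] - par[2L] * log(freqs) else numeric(length(freqs))
  G <- vector("list", k)
  for (i in seq_len(k)) {
    j <- off + 3L * (i - 1L)
    G[[i]] <- gaussian_peak(freqs, par[j + 1L], par[j + 2L], par[j + 3L])
    model <- model + G[[i]]
  }
  r <- model - y   # d SSE / d model = 2 r
  grad <- numeric(length(par))
  if (ap) {
    grad[1L] <- 2 * sum(r)
    grad[2L] <- -2 * sum(r * log(freqs))
  }
  for (i in seq_len(k)) {
    j <- off + 3L * (i - 1L)
    c_i <- par[j + 1L]; w_i <- par[j + 3L]
    dfc <- (freqs - c_i)
    grad[j + 1L] <- 2 * sum(r * G[[i]] * dfc / w_i^2)
    grad[j + 2L] <- 2 * sum(r * G[[i]] / par[j + 2L])
    grad[j + 3L] <- 2 * sum(r * G[[i]] * dfc^2 / w_i^3)
  }
  grad
}

# Joint least-squares refit of all Gaussians against the residual spectrum.
refit_peaks <- function(freqs, resid, peaks, bw_lim, max_iter) {
  if (!length(peaks)) return(peaks)
  par0 <- unlist(lapply(peaks, function(p) c(p$c, p$p, p$w)))
  k <- length(peaks)
  lower <- rep(c(min(freqs), 1e-6, bw_lim[1L]), k)
  upper <- rep(c(max(freqs), Inf, bw_lim[2L]), k)
  op <- stats::optim(par0, gauss_model_sse, gr = gauss_model_grad,
                     freqs = freqs, y = resid, k = k,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = max_iter, factr = 1e3))
  lapply(seq_len(k), function(i) {
    j <- 3L * (i - 1L)
    list(c = op$par[j + 1L], p = op$par[j + 2L], w = op$par[j + 3L])
  })
}

#' Extract Gaussian peaks from a flattened (aperiodic-removed) spectrum
#'
#' Iteratively locates the residual maximum, stops when it falls below
#' `max(min_height, rel_thresh * SD(residual))`, seeds a Gaussian from the
#' local half-height width, subtracts it and repeats (at most `max_peaks`
#' times); all Gaussians are then refit jointly by least squares.
#'
#' @param residual_log numeric vector: log spectrum minus aperiodic fit.
#' @param freqs frequencies (Hz).
#' @param config a [spec_config()].
#' @return A list of peaks, each `list(c = center Hz, p = log-power height,
#'   w = bandwidth Hz)`, in descending height order; possibly empty.
#' @export
extract_peaks <- function(residual_log, freqs, config = spec_config()) {
  stopifnot(length(residual_log) == length(freqs))
  resid <- residual_log
  peaks <- list()
  df <- mean(diff(freqs))
  for (it in seq_len(config$max_peaks)) {
    thresh <- max(config$min_height, config$rel_thresh * stats::sd(resid))
    i_max <- which.max(resid)
    height <- resid[i_max]
    if (!is.finite(height) || height < thresh) break
    c0 <- freqs[i_max]
    # half-height width on the shallower side, symmetric assumption
    half <- height / 2
    i_r <- i_max; while (i_r < length(resid) && resid[i_r] > half) i_r <- i_r + 1L
    i_l <- i_max; while (i_l > 1L && resid[i_l] > half) i_l <- i_l - 1L
    hw <- min(abs(freqs[i_r] - c0), abs(c0 - freqs[i_l]))
    if (hw <= 0) hw <- df
    w0 <- hw / sqrt(2 * log(2))       # half width at half maximum -> SD
    w0 <- min(max(w0, config$bw_lim[1L]), config$bw_lim[2L])
    peaks[[length(peaks) + 1L]] <- list(c = c0, p = height, w = w0)
    resid <- resid - gaussian_peak(freqs, c0, height, w0)
  }
  peaks <- refit_peaks(freqs, residual_log, peaks, config$bw_lim,
                       config$max_iter)
  # drop peaks the joint refit shrank below the absolute threshold, then
  # merge overlapping pairs (a single broad bump can split into two seeded
  # Gaussians); keep the stronger of any pair closer than 0.75 summed SDs
  # and refit until stable
  repeat {
    peaks <- Filter(function(p) p$p >= config$min_height, peaks)
    if (length(peaks) < 2L) break
    drop_idx <- NULL
    for (i in seq_along(peaks)) {
      for (j in seq_along(peaks)) {
        if (i < j &&
            abs(peaks[[i]]$c - peaks[[j]]$c) <
              0.75 * (peaks[[i]]$w + peaks[[j]]$w)) {
          drop_idx <- if (peaks[[i]]$p >= peaks[[j]]$p) j else i
          break
        }
      }
      if (!is.null(drop_idx)) break
    }
    if (is.null(drop_idx)) break
    peaks <- refit_peaks(freqs, residual_log, peaks[-drop_idx],
                         config$bw_lim, config$max_iter)
  }
  peaks <- Filter(function(p) p$p >= config$min_height, peaks)
  peaks[order(vapply(peaks, `[[`, numeric(1), "p"), decreasing = TRUE)]
}

#' Decompose a log power spectrum into aperiodic and periodic parts
#'
#' Full spectral parameterization: robust aperiodic fit, Gaussian peak
#' extraction on the flattened residual, aperiodic refit on the peak-removed
#' spectrum, and goodness of fit of the combined model
#' `PSD(F) = L(F) + sum_n G_n(F)` (all on the natural-log scale).
#'
#' @param psd_log numeric vector of log power values.
#' @param freqs frequencies (Hz).
#' @param config a [spec_config()].
#' @return An object of class `"spectral_model"`: `aperiodic`
#'   ([fit_aperiodic()] result), `peaks` (list, possibly empty), `r2`,
#'   `fitted` (model spectrum) and `freqs`.
#' @examples
#' g <- frequency_grid()
#' y <- 2 - log(g$freqs) + 0.6 * exp(-(g$freqs - 10)^2 / (2 * 1.2^2))
#' m <- fit_spectrum(y, g$freqs)
#' c(m$aperiodic$b, m$aperiodic$chi, length(m$peaks))
#' @export
fit_spectrum <- function(psd_log, freqs, config = spec_config()) {
  ap1 <- fit_aperiodic(psd_log, freqs, config = config)
  resid <- psd_log - aperiodic_values(freqs, ap1$b, ap1$chi, ap1$k)
  peaks <- extract_peaks(resid, freqs, config)
  peak_model <- peaks_values(freqs, peaks)
  # final aperiodic pass on the peak-removed spectrum (plain fit; peaks gone)
  p2 <- fit_aperiodic_plain(freqs, psd_log - peak_model, config$mode,
                            config$max_iter)
  # joint polish of aperiodic + peaks on the raw spectrum (fixed mode has an
  # analytic gradient; knee mode keeps the staged estimates)
  if (config$mode == "fixed" && length(peaks)) {
    k_pk <- length(peaks)
    par0 <- c(p2$b, p2$chi,
              unlist(lapply(peaks, function(p) c(p$c, p$p, p$w))))
    lower <- c(-Inf, 0, rep(c(min(freqs), 1e-6, config$bw_lim[1L]), k_pk))
    upper <- c(Inf, Inf, rep(c(max(freqs), Inf, config$bw_lim[2L]), k_pk))
    op <- stats::optim(par0, gauss_model_sse, gr = gauss_model_grad,
                       freqs = freqs, y = psd_log, k = k_pk, ap = TRUE,
                       method = "L-BFGS-B", lower = lower, upper = upper,
                       control = list(maxit = config$max_iter, factr = 1e2))
    p2$b <- op$par[1L]; p2$chi <- op$par[2L]
    peaks <- lapply(seq_len(k_pk), function(i) {
      j <- 2L + 3L * (i - 1L)
      list(c = op$par[j + 1L], p = op$par[j + 2L], w = op$par[j + 3L])
    })
    peaks <- Filter(function(p) p$p >= config$min_height, peaks)
    peaks <- peaks[order(vapply(peaks, `[[`, numeric(1), "p"),
                         decreasing = TRUE)]
    peak_model <- peaks_values(freqs, peaks)
  }
  ap <- structure(list(b = p2$b, k = p2$k, chi = p2$chi, mode = config$mode,
                       fit_error = NA_real_, n_used = length(freqs)),
                  class = "aperiodic_fit")
  fitted <- aperiodic_values(freqs, ap$b, ap$chi, ap$k) + peak_model
  ap$fit_error <- mean(abs(psd_log - fitted))
  sst <- sum((psd_log - mean(psd_log))^2)
  r2 <- if (sst > 0) 1 - sum((psd_log - fitted)^2) / sst else 1
  structure(list(aperiodic = ap, peaks = peaks, r2 = r2, fitted = fitted,
                 freqs = freqs),
            class = "spectral_model")
}

#' @export
print.spectral_model <- function(x, ...) {
  cat(sprintf("Spectral model: offset %.4g, exponent %.4g, %d peak(s), R2 %.4f\n",
              x$aperiodic$b, x$aperiodic$chi, length(x$peaks), x$r2))
  for (p in x$peaks)
    cat(sprintf("  peak: center %.3g Hz, power %.3g, bandwidth %.3g Hz\n",
                p$c, p$p, p$w))
  invisible(x)
}

#' @export
plot.spectral_model <- function(x, y, psd_log = NULL, ...) {
  plot(x$freqs, x$fitted, type = "l", col = "firebrick", lwd = 2,
       xlab = "Frequency (Hz)", ylab = "log power", ...)
  ap <- x$aperiodic
  lines(x$freqs, aperiodic_values(x$freqs, ap$b, ap$chi, ap$k),
        lty = 2, col = "grey40")
  if (!is.null(psd_log)) points(x$freqs, psd_log, pch = 16, cex = 0.5)
  invisible(x)
}

#' Dominant peak of a spectral model
#'
#' Returns the peak with the largest power; ties are broken in favour of the
#' lower center frequency.  `NULL` when no peak was detected.
#'
#' @param model a [fit_spectrum()] result.
#' @return A peak `list(c, p, w)` or `NULL`.
#' @export
select_dominant_peak <- function(model) {
  stopifnot(inherits(model, "spectral_model"))
  if (!length(model$peaks)) return(NULL)
  pw <- vapply(model$peaks, `[[`, numeric(1), "p")
  cf <- vapply(model$peaks, `[[`, numeric(1), "c")
  best <- order(-pw, cf)[1L]
  model$peaks[[best]]
}

#' Fit spectral models for every subject and channel of a cohort
#'
#' @param psd a log-scale [power_spectra()] object.
#' @param config a [spec_config()].
#' @return A subject x channel matrix-like list of `"spectral_model"`
#'   objects with class `"spectral_models"`, carrying `dim` and the source
#'   channel labels.
#' @export
fit_cohort_spectra <- function(psd, config = spec_config()) {
  stopifnot(inherits(psd, "power_spectra"))
  if (psd$scale != "log") psd <- log_transform(psd)
  d <- dim(psd$values)
  models <- vector("list", d[1L] * d[2L])
  dim(models) <- c(d[1L], d[2L])
  for (s in seq_len(d[1L]))
    for (c_i in seq_len(d[2L]))
      models[[s, c_i]] <- fit_spectrum(psd$values[s, c_i, ], psd$grid$freqs,
                                       config)
  structure(models, class = "spectral_models", channels = psd$channels,
            subject_id = psd$meta$subject_id)
}
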