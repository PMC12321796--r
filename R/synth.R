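#' Configuration for the synthetic cohort generator
#'
#' The generator emulates lifespan resting-EEG log power spectra on the
#' default 47-bin grid and 18-electrode montage: an age-dependent aperiodic
#' power law (exponent and offset both falling linearly in log10(age), with
#' subject-level jitter), an alpha peak whose center frequency rises through
#' childhood to a plateau and whose power is posteriorly dominant with an
#' age-increasing gradient, optional theta- and beta-band Gaussian bumps
#' (the theta bump's electrode profile is coupled to the alpha-power profile
#' with an age-increasing coupling, so inter-feature dependencies also carry
#' age information), a smooth anterior-posterior offset gradient, and
#' i.i.d. Gaussian noise in the log domain.  Ages follow a youth-heavy
#' two-component Beta mixture over 5-97 years.
#'
#' @param n number of subjects.
#' @param seed integer seed; identical config + seed reproduces the cohort
#'   bit for bit.
#' @param age_range lifespan limits in years.
#' @param age_mix mixture weight of the young component.
#' @param exponent_ref exponent at the range endpoints: falls linearly in
#'   log10(age) from `exponent_ref[1]` (at the young end) to
#'   `exponent_ref[2]` (at the old end).
#' @param offset_ref offset endpoints, same parameterization.
#' @param subject_sd subject-level SD of exponent and offset jitter.
#' @param channel_sd channel-level SD of exponent jitter.
#' @param offset_gradient amplitude of the anterior-posterior offset
#'   gradient (log units).
#' @param alpha_presence probability a subject expresses an alpha peak.
#' @param alpha_power,alpha_bw mean alpha peak height (log units) and
#'   bandwidth (Hz).
#' @param theta_presence,beta_presence probabilities of secondary bumps.
#' @param noise_sd per-bin log-domain noise SD.
#' @return List of class `"cohort_config"`.
#' @export
cohort_config <- function(n = 400L, seed = 7L, age_range = c(5, 97),
                          age_mix = 0.7, exponent_ref = c(2.0, 1.0),
                          offset_ref = c(1.5, 0.5), subject_sd = 0.08,
                          channel_sd = 0.02, offset_gradient = 0.2,
                          alpha_presence = 0.95, alpha_power = 0.6,
                          alpha_bw = 1.2, theta_presence = 0.9,
                          beta_presence = 0.9, noise_sd = 0.05) {
  stopifnot(n >= 1, age_range[1L] > 0, age_range[2L] > age_range[1L],
            subject_sd >= 0, channel_sd >= 0, noise_sd >= 0,
            alpha_presence >= 0, alpha_presence <= 1)
  structure(as.list(environment()), class = "cohort_config")
}

# Linear-in-log10(age) trajectory through (age_range[1], ref[1]) and
# (age_range[2], ref[2]).
log_age_trajectory <- function(age, age_range, ref) {
  la <- log10(age); la1 <- log10(age_range[1L]); la2 <- log10(age_range[2L])
  ref[1L] + (ref[2L] - ref[1L]) * (la - la1) / (la2 - la1)
}

# Alpha center frequency: 8 Hz at age 5 rising to 10.5 Hz at 25, plateau.
alpha_center <- function(age) {
  8 + 2.5 * pmin(1, pmax(0, log10(age / 5) / log10(25 / 5)))
}

# Theta-alpha coupling strength rho(age): 0.1 at the young end to 0.9 at the
# old end, linear in log10(age).
theta_alpha_coupling <- function(age, age_range) {
  pmin(0.9, pmax(0.1, log_age_trajectory(age, age_range, c(0.1, 0.9))))
}

#' Generate a synthetic lifespan EEG cohort
#'
#' @param config a [cohort_config()].
#' @return List of class `"synth_cohort"`: `spectra` (log-scale
#'   [power_spectra()]), `meta`, and `truth` -- a list with per-subject ages
#'   and per-subject-x-channel true aperiodic parameters (`b`, `chi`) and
#'   alpha-peak parameters (`alpha_c`, `alpha_p`, `alpha_w`, `alpha_present`).
#' @examples
#' cohort <- make_cohort(cohort_config(n = 20, seed = 1))
#' dim(cohort$spectra$values)  # 20 x 18 x 47
#' @export
make_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  grid <- frequency_grid()
  channels <- eeg_channels()
  n_ch <- length(channels)
  ap <- ap_scores()                     # anterior(-1)..posterior(+1)
  withr_seed(config$seed, {
    n <- config$n
    comp <- stats::rbinom(n, 1L, config$age_mix)
    ages <- ifelse(comp == 1L,
                   stats::rbeta(n, 1.8, 6), stats::rbeta(n, 3, 3))
    ages <- config$age_range[1L] +
      diff(config$age_range) * pmin(pmax(ages, 1e-3), 1 - 1e-3)
    chi_age <- log_age_trajectory(ages, config$age_range, config$exponent_ref)
    b_age <- log_age_trajectory(ages, config$age_range, config$offset_ref)
    chi_subj <- pmax(0.2, chi_age + stats::rnorm(n, 0, config$subject_sd))
    b_subj <- b_age + stats::rnorm(n, 0, config$subject_sd)
    vals <- array(0, dim = c(n, n_ch, grid$n_bins))
    tb <- matrix(NA_real_, n, n_ch); tchi <- matrix(NA_real_, n, n_ch)
    ta_c <- matrix(NA_real_, n, n_ch); ta_p <- matrix(NA_real_, n, n_ch)
    ta_w <- matrix(NA_real_, n, n_ch)
    alpha_present <- stats::runif(n) < config$alpha_presence
    theta_present <- stats::runif(n) < config$theta_presence
    beta_present <- stats::runif(n) < config$beta_presence
    rho <- theta_alpha_coupling(ages, config$age_range)
    post <- (ap + 1) / 2                # 0 (front) .. 1 (back)
    for (s in seq_len(n)) {
      # offset electrode profile: smooth gradient plus subject-specific
      # spatial variation; the exponent profile tracks it with the same
      # age-dependent coupling rho used below (high-precision features, so
      # this dependency survives fitting noise)
      b_var <- stats::rnorm(n_ch, 0, 0.08)
      b_ch <- b_subj[s] + config$offset_gradient * ap + b_var
      b_dev <- (b_var - mean(b_var)) / max(stats::sd(b_var), 1e-6)
      chi_ch <- pmax(0.1, chi_subj[s] + 2 * config$channel_sd *
                       (rho[s] * b_dev + sqrt(1 - rho[s]^2) *
                          stats::rnorm(n_ch)))
      # posterior alpha dominance grows with age
      grad_gain <- log_age_trajectory(ages[s], config$age_range, c(0.2, 0.8))
      a_pow <- config$alpha_power * (1 + grad_gain * (post - 0.5)) +
        stats::rnorm(n_ch, 0, 0.05)
      a_pow <- pmax(0.1, a_pow)
      a_dev <- (a_pow - mean(a_pow)) / max(stats::sd(a_pow), 1e-6)
      # One latent coupling strength rho(age) ties several oscillatory
      # profiles to the alpha-power electrode profile: the alpha bandwidth
      # and center-frequency profiles and the theta- and beta-bump power
      # profiles each follow rho * a_dev plus independent noise.  Every
      # coupled profile keeps an age-flat mean, so this age signal lives in
      # the inter-feature dependencies across electrodes rather than in any
      # marginal feature level -- the structure the dependency (ODC)
      # regressions are designed to expose.
      couple <- function(noise_sd = 1) rho[s] * a_dev +
        sqrt(1 - rho[s]^2) * stats::rnorm(n_ch, 0, noise_sd)
      a_cf <- alpha_center(ages[s]) + stats::rnorm(1L, 0, 0.3) +
        0.5 * couple()
      a_bw <- config$alpha_bw * stats::runif(1L, 0.95, 1.05) +
        0.25 * couple()
      a_bw <- pmin(pmax(a_bw, 0.6), 2.5)
      spec <- outer(-chi_ch, log(grid$freqs)) + b_ch
      if (alpha_present[s]) {
        for (c_i in seq_len(n_ch))
          spec[c_i, ] <- spec[c_i, ] +
            gaussian_peak(grid$freqs, a_cf[c_i], a_pow[c_i], a_bw[c_i])
        ta_c[s, ] <- a_cf; ta_p[s, ] <- a_pow; ta_w[s, ] <- a_bw
      }
      if (theta_present[s]) {
        t_pow <- pmax(0.05, 0.25 + 0.1 * couple())
        t_cf <- stats::runif(1L, 5.5, 6.5)
        for (c_i in seq_len(n_ch))
          spec[c_i, ] <- spec[c_i, ] +
            gaussian_peak(grid$freqs, t_cf, t_pow[c_i], 1.1)
      }
      if (beta_present[s]) {
        b_cf <- stats::runif(1L, 14, 17)
        b_pow <- pmax(0.05, 0.2 + 0.1 * couple())
        for (c_i in seq_len(n_ch))
          spec[c_i, ] <- spec[c_i, ] +
            gaussian_peak(grid$freqs, b_cf, b_pow[c_i], 1.5)
      }
      spec <- spec + matrix(stats::rnorm(n_ch * grid$n_bins, 0,
                                         config$noise_sd), n_ch)
      vals[s, , ] <- spec
      tb[s, ] <- b_ch; tchi[s, ] <- chi_ch
    }
    meta <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                       age = ages,
                       sex = sample(c("F", "M"), n, replace = TRUE),
                       site = "synthetic", stringsAsFactors = FALSE)
    spectra <- power_spectra(vals, grid, channels, meta, scale = "log")
    truth <- list(age = ages, b = tb, chi = tchi, alpha_c = ta_c,
                  alpha_p = ta_p, alpha_w = ta_w,
                  alpha_present = alpha_present,
                  theta_present = theta_present,
                  theta_alpha_rho = rho)
    structure(list(spectra = spectra, meta = meta, truth = truth,
                   config = config),
              class = "synth_cohort")
  })
}

#' Generate Hermitian cross-spectra consistent with target powers
#'
#' Builds, per frequency, `D^1/2 C D^1/2` where `D` holds the target
#' channel powers of a generated cohort and `C` is a fixed Hermitian
#' correlation structure (exponential decay in channel distance with a
#' small imaginary antisymmetric part).  Exercises the referencing and
#' diagonal-extraction preprocessing.
#'
#' @param config a [cohort_config()]; `n` subjects on the raw 19-channel
#'   montage (uniform power is assumed on the Pz channel appended for
#'   referencing tests).
#' @param decay correlation decay rate between channel indices.
#' @return A [cross_spectra()] object (19 channels including Pz).
#' @export
make_cross_spectra <- function(config = cohort_config(n = 4L), decay = 0.4) {
  cohort <- make_cohort(config)
  lin <- exp(cohort$spectra$values)
  d <- dim(lin)
  channels <- c(cohort$spectra$channels, "Pz")
  n_ch <- length(channels)
  idx <- seq_len(n_ch)
  Cmat <- exp(-decay * abs(outer(idx, idx, "-"))) +
    1i * 0.05 * sign(outer(idx, idx, "-")) *
    exp(-decay * abs(outer(idx, idx, "-")))
  # Hermitian positive definite by construction for small imaginary part
  ev <- eigen(Cmat, symmetric = FALSE, only.values = TRUE)$values
  if (min(Re(ev)) <= 0) stop("correlation structure not positive definite")
  out <- array(0i, dim = c(d[1L], n_ch, n_ch, d[3L]))
  for (s in seq_len(d[1L])) {
    for (f in seq_len(d[3L])) {
      pw <- c(lin[s, , f], mean(lin[s, , f]))   # Pz gets the channel mean
      Dh <- sqrt(pw)
      out[s, , , f] <- (Dh %o% Dh) * Cmat
    }
  }
  cross_spectra(out, cohort$spectra$grid, channels, cohort$meta)
}

#' Inject gross outliers into a cohort's spectra
#'
#' Shifts and tilts the log spectra of a random subject subset: the whole
#' spectrum is displaced by `magnitude` log units with a random sign and the
#' spectral slope is distorted, emulating gross artifacts.
#'
#' @param psd a log-scale [power_spectra()] object.
#' @param fraction fraction of subjects to corrupt (0 < fraction < 0.5).
#' @param magnitude displacement in log-power units.
#' @param seed integer seed.
#' @return List: `spectra` (corrupted copy) and `outliers` (subject indices).
#' @export
inject_outliers <- function(psd, fraction = 0.05, magnitude = 3, seed = 1L) {
  stopifnot(inherits(psd, "power_spectra"), psd$scale == "log")
  if (fraction <= 0) return(list(spectra = psd, outliers = integer(0)))
  if (fraction >= 0.5) stop("fraction must be below 0.5")
  d <- dim(psd$values)
  withr_seed(seed, {
    n_out <- max(1L, round(fraction * d[1L]))
    idx <- sort(sample.int(d[1L], n_out))
    v <- psd$values
    for (s in idx) {
      sgn <- sample(c(-1, 1), 1L)
      tilt <- stats::runif(1L, 0.5, 1.5) * sgn
      lf <- log(psd$grid$freqs); lf <- (lf - mean(lf)) / stats::sd(lf)
      v[s, , ] <- v[s, , ] + sgn * magnitude +
        matrix(rep(tilt * lf, each = d[2L]), d[2L])
    }
    list(spectra = power_spectra(v, psd$grid, psd$channels, psd$meta,
                                 scale = "log"),
         outliers = idx)
  })
}
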