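#' Frequency band definitions
#'
#' The four analysis bands: delta [1, 4), theta [4, 8), alpha [8, 12) and
#' beta [12, 20) Hz.  Bands are half-open on the right so shared edges are
#' never counted twice; beta is truncated at the grid maximum (19.14 Hz on
#' the default grid) although nominally defined to 20 Hz.
#'
#' @return A named list of `c(lo, hi)` pairs.
#' @export
band_defs <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12), beta = c(12, 20))
}

#' Canonical oscillatory feature names and groups
#'
#' The 13 per-electrode oscillatory features (OSFs) in canonical order with
#' their group labels: AP (aperiodic exponent, offset), PP (dominant-peak
#' center frequency, power, bandwidth), PR (theta/beta, delta/theta,
#' delta/alpha, theta/alpha band-power ratios), RP (relative delta, theta,
#' alpha, beta power).
#'
#' @return `osf_feature_names()`: character vector of 13 names.
#'   `osf_feature_groups()`: named factor-like character vector mapping each
#'   feature to its group.
#' @export
osf_feature_names <- function() {
  c("AP-exponent", "AP-offset", "PP-cf", "PP-power", "PP-bw",
    "PR-theta/beta", "PR-delta/theta", "PR-delta/alpha", "PR-theta/alpha",
    "RP-delta", "RP-theta", "RP-alpha", "RP-beta")
}

#' @rdname osf_feature_names
#' @export
osf_feature_groups <- function() {
  g <- c(rep("AP", 2L), rep("PP", 3L), rep("PR", 4L), rep("RP", 4L))
  names(g) <- osf_feature_names()
  g
}

#' Band-limited absolute power
#'
#' Sum of linear power over the grid bins with `lo <= f < hi`.
#'
#' @param psd_linear numeric vector of linear power values.
#' @param freqs frequencies (Hz).
#' @param band numeric `c(lo, hi)` or a name from [band_defs()].
#' @return Summed linear power (scalar).
#' @examples
#' g <- frequency_grid()
#' band_power(rep(1, g$n_bins), g$freqs, "delta")  # 8 bins
#' @export
band_power <- function(psd_linear, freqs, band) {
  if (is.character(band)) band <- band_defs()[[match.arg(band, names(band_defs()))]]
  stopifnot(length(psd_linear) == length(freqs), length(band) == 2L)
  idx <- freqs >= band[1L] & freqs < band[2L]
  if (!any(idx)) stop("band lies entirely outside the frequency grid")
  sum(psd_linear[idx])
}

#' Power ratio between two bands
#'
#' @param psd_linear linear power vector.
#' @param freqs frequencies (Hz).
#' @param num,den numerator / denominator bands (names or `c(lo, hi)`).
#' @return `band_power(num) / band_power(den)`.
#' @export
power_ratio <- function(psd_linear, freqs, num, den) {
  dp <- band_power(psd_linear, freqs, den)
  if (dp <= 0) stop("zero denominator band power")
  band_power(psd_linear, freqs, num) / dp
}

#' Relative band power
#'
#' Band power as a fraction of the total power over the full analysis range;
#' the four relative powers over the tiling bands sum to 1.
#'
#' @inheritParams power_ratio
#' @param band the band of interest.
#' @return Fraction in (0, 1].
#' @export
relative_power <- function(psd_linear, freqs, band) {
  total <- sum(psd_linear)
  if (total <= 0) stop("zero total power")
  band_power(psd_linear, freqs, band) / total
}

osf_row <- function(model, psd_linear, freqs) {
  ap <- model$aperiodic
  pk <- select_dominant_peak(model)
  c(ap$chi, ap$b,
    if (is.null(pk)) c(NA_real_, NA_real_, NA_real_) else c(pk$c, pk$p, pk$w),
    power_ratio(psd_linear, freqs, "theta", "beta"),
    power_ratio(psd_linear, freqs, "delta", "theta"),
    power_ratio(psd_linear, freqs, "delta", "alpha"),
    power_ratio(psd_linear, freqs, "theta", "alpha"),
    relative_power(psd_linear, freqs, "delta"),
    relative_power(psd_linear, freqs, "theta"),
    relative_power(psd_linear, freqs, "alpha"),
    relative_power(psd_linear, freqs, "beta"))
}

#' Build the subject x electrode x feature OSF table
#'
#' Computes the 13 oscillatory features for every subject and electrode.
#' Channels with no detected peak get the dominant-peak (PP) features
#' imputed with the subject's median over channels that do have a peak; if a
#' subject has no peaks at all, the cohort median per feature is used
#' (downstream dependency regressions require complete tables).
#'
#' @param models a [fit_cohort_spectra()] result.
#' @param psd the matching [power_spectra()] object (any scale).
#' @return An object of class `"osf_table"`: 3-d array subject x electrode
#'   x 13 with `feature_names`, `groups` and `meta` attached.
#' @export
build_osf_table <- function(models, psd) {
  stopifnot(inherits(models, "spectral_models"), inherits(psd, "power_spectra"))
  d <- dim(psd$values)
  if (!all(dim(models) == d[1:2])) stop("model and spectra dimensions differ")
  lin <- if (psd$scale == "linear") psd$values else exp(psd$values)
  fn <- osf_feature_names()
  out <- array(NA_real_, dim = c(d[1L], d[2L], 13L),
               dimnames = list(psd$meta$subject_id, psd$channels, fn))
  for (s in seq_len(d[1L]))
    for (c_i in seq_len(d[2L]))
      out[s, c_i, ] <- osf_row(models[[s, c_i]], lin[s, c_i, ], psd$grid$freqs)
  # impute missing PP triplets
  for (j in 3:5) {
    for (s in seq_len(d[1L])) {
      row <- out[s, , j]
      if (anyNA(row)) {
        med <- stats::median(row, na.rm = TRUE)
        if (is.na(med)) med <- stats::median(out[, , j], na.rm = TRUE)
        if (is.na(med)) med <- 0
        out[s, is.na(row), j] <- med
      }
    }
  }
  structure(out, class = "osf_table", feature_names = fn,
            groups = osf_feature_groups(), meta = psd$meta)
}

#' Electrode-wise correlation of features with age, and region aggregates
#'
#' Pearson correlation between each (electrode, feature) column and age,
#' plus region-level importance as the mean correlation over the member
#' electrodes of each scalp region.
#'
#' @param osf an [build_osf_table()] result.
#' @param ages numeric vector of ages aligned with the table's subjects.
#' @return A list of class `"importance_map"`: `pcc` (electrode x feature)
#'   and `region_pcc` (region x feature).
#' @export
pcc_importance <- function(osf, ages = NULL) {
  stopifnot(inherits(osf, "osf_table"))
  if (is.null(ages)) ages <- attr(osf, "meta")$age
  d <- dim(osf)
  if (length(ages) != d[1L]) stop("ages must align with subjects")
  if (d[1L] < 3L) stop("need at least 3 subjects")
  pcc <- matrix(NA_real_, d[2L], d[3L],
                dimnames = dimnames(osf)[2:3])
  for (c_i in seq_len(d[2L])) {
    for (j in seq_len(d[3L])) {
      v <- osf[, c_i, j]
      if (stats::sd(v) == 0) {
        warning(sprintf("zero-variance feature %s at %s; correlation set to 0",
                        dimnames(osf)[[3L]][j], dimnames(osf)[[2L]][c_i]))
        pcc[c_i, j] <- 0
      } else {
        pcc[c_i, j] <- stats::cor(v, ages)
      }
    }
  }
  regions <- channel_regions()
  reg_names <- unique(unname(regions))
  region_pcc <- matrix(NA_real_, length(reg_names), d[3L],
                       dimnames = list(reg_names, dimnames(osf)[[3L]]))
  electrodes <- dimnames(osf)[[2L]]
  for (r in reg_names) {
    members <- intersect(names(regions)[regions == r], electrodes)
    region_pcc[r, ] <- colMeans(pcc[members, , drop = FALSE])
  }
  structure(list(pcc = pcc, region_pcc = region_pcc),
            class = "importance_map")
}

#' @export
print.importance_map <- function(x, ...) {
  cat("Electrode-wise feature-age correlations (region means):\n")
  print(round(x$region_pcc, 3))
  invisible(x)
}
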