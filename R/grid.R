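#' Frequency grid
#'
#' A regular frequency axis for power spectra.  The default analysis grid is
#' the 47-bin dyadic grid used for lifespan EEG cross-spectra: step
#' 0.390625 Hz (= 100/256), bins spanning 1.171875 to 19.140625 Hz, usually
#' printed rounded as 1.17--19.14 Hz at 0.39 Hz.
#'
#' @param start_hz frequency of the first bin (Hz).
#' @param step_hz bin spacing (Hz), must be positive.
#' @param n_bins number of bins (>= 2).
#' @return An object of class `"frequency_grid"` with elements `start_hz`,
#'   `step_hz`, `n_bins` and the evaluated `freqs` vector.
#' @examples
#' g <- frequency_grid()
#' g$n_bins      # 47
#' range(g$freqs)
#' @export
frequency_grid <- function(start_hz = 1.171875, step_hz = 0.390625, n_bins = 47L) {
  stopifnot(is.numeric(start_hz), length(start_hz) == 1L, is.finite(start_hz))
  if (!is.numeric(step_hz) || length(step_hz) != 1L || step_hz <= 0)
    stop("step_hz must be a positive number")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L) stop("n_bins must be >= 2")
  structure(
    list(start_hz = start_hz, step_hz = step_hz, n_bins = n_bins,
         freqs = start_hz + (seq_len(n_bins) - 1L) * step_hz),
    class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("Frequency grid: %d bins, %.6g-%.6g Hz, step %.6g Hz\n",
              x$n_bins, x$freqs[1L], x$freqs[x$n_bins], x$step_hz))
  invisible(x)
}

#' @rdname frequency_grid
#' @param x object to test.
#' @export
is_frequency_grid <- function(x) inherits(x, "frequency_grid")

# Grid equality up to floating point (used when checking file consistency).
grid_equal <- function(a, b, tol = 1e-9) {
  a$n_bins == b$n_bins &&
    abs(a$start_hz - b$start_hz) < tol &&
    abs(a$step_hz - b$step_hz) < tol
}

#' Canonical electrode sets and scalp regions
#'
#' The raw 10--20 montage has 19 electrodes; after average referencing the
#' common mode is removed (rank deficiency by one) and Pz is discarded,
#' leaving the 18-electrode analysis set.  `eeg_channels()` returns either
#' set in canonical order; `channel_regions()` maps the 18 analysis
#' electrodes onto five scalp regions.
#'
#' @param set `"analysis"` (18 electrodes, default) or `"raw"` (19,
#'   including Pz).
#' @return `eeg_channels()`: character vector of electrode labels.
#'   `channel_regions()`: named character vector, region per electrode.
#' @examples
#' eeg_channels()
#' table(channel_regions())
#' @export
eeg_channels <- function(set = c("analysis", "raw")) {
  set <- match.arg(set)
  ch <- c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
          "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Cz")
  if (set == "raw") c(ch, "Pz") else ch
}

#' @rdname eeg_channels
#' @export
channel_regions <- function() {
  regions <- list(
    frontal   = c("Fp1", "Fp2", "F7", "F8", "F3", "F4", "Fz"),
    central   = c("C3", "C4", "Cz"),
    parietal  = c("P3", "P4"),
    occipital = c("O1", "O2"),
    temporal  = c("T3", "T4", "T5", "T6"))
  out <- rep(names(regions), lengths(regions))
  names(out) <- unlist(regions, use.names = FALSE)
  out[eeg_channels()]
}

# Anterior-posterior score per analysis electrode in [-1, 1]; used by the
# synthetic generator for smooth scalp gradients (frontal -1 .. occipital +1).
ap_scores <- function() {
  s <- c(Fp1 = -1, Fp2 = -1, F7 = -0.6, F8 = -0.6, F3 = -0.6, F4 = -0.6,
         Fz = -0.6, C3 = 0, C4 = 0, Cz = 0, T3 = 0, T4 = 0,
         T5 = 0.5, T6 = 0.5, P3 = 0.5, P4 = 0.5, O1 = 1, O2 = 1)
  s[eeg_channels()]
}
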