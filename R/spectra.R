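#' Power spectra tensor
#'
#' Container for subject x channel x frequency power spectra on a fixed
#' [frequency_grid()], in either linear or (natural) log power units, with
#' aligned subject metadata.
#'
#' @param values numeric array, subject x channel x frequency; all finite,
#'   and strictly positive when `scale = "linear"`.
#' @param grid a [frequency_grid()] whose `n_bins` matches `dim(values)[3]`.
#' @param channels character vector of electrode labels matching
#'   `dim(values)[2]`; no duplicates.
#' @param meta data frame with columns `subject_id`, `age`, `sex`, `site`;
#'   one row per subject in tensor order.  Created with defaults if `NULL`.
#' @param scale `"linear"` or `"log"` power units.
#' @return An object of class `"power_spectra"`.
#' @seealso [read_spectra()], [diagonal_power()], [global_scale_correct()]
#' @export
power_spectra <- function(values, grid, channels, meta = NULL,
                          scale = c("log", "linear")) {
  scale <- match.arg(scale)
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (!is_frequency_grid(grid)) stop("grid must be a frequency_grid")
  d <- dim(values)
  if (d[3L] != grid$n_bins) stop("third dimension must match grid n_bins")
  channels <- as.character(channels)
  if (anyDuplicated(channels)) stop("duplicate channel labels")
  if (d[2L] != length(channels)) stop("second dimension must match channels")
  if (!all(is.finite(values))) stop("power values must all be finite")
  if (scale == "linear" && any(values <= 0))
    stop("linear-power values must be strictly positive")
  if (is.null(meta)) {
    meta <- data.frame(subject_id = sprintf("S%03d", seq_len(d[1L])),
                       age = NA_real_, sex = "unknown", site = "unknown",
                       stringsAsFactors = FALSE)
  }
  meta <- validate_meta(meta, n = d[1L])
  dimnames(values) <- list(meta$subject_id, channels, NULL)
  structure(list(values = values, grid = grid, channels = channels,
                 meta = meta, scale = scale),
            class = "power_spectra")
}

validate_meta <- function(meta, n = NULL) {
  stopifnot(is.data.frame(meta))
  for (col in c("subject_id", "age", "sex", "site")) {
    if (!col %in% names(meta)) {
      meta[[col]] <- switch(col, subject_id = sprintf("S%03d", seq_len(nrow(meta))),
                            age = NA_real_, "unknown")
    }
  }
  meta$subject_id <- as.character(meta$subject_id)
  meta$age <- as.numeric(meta$age)
  if (anyDuplicated(meta$subject_id)) stop("subject_ids must be unique")
  if (any(!is.na(meta$age) & meta$age <= 0)) stop("ages must be positive")
  if (!is.null(n) && nrow(meta) != n)
    stop("metadata rows must match number of subjects")
  rownames(meta) <- NULL
  meta
}

#' @export
print.power_spectra <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("Power spectra: %d subjects x %d channels x %d bins (%s scale)\n",
              d[1L], d[2L], d[3L], x$scale))
  cat(sprintf("  grid %.4g-%.4g Hz; ages %s\n", x$grid$freqs[1L],
              x$grid$freqs[x$grid$n_bins],
              if (all(is.na(x$meta$age))) "unknown"
              else sprintf("%.3g-%.3g y", min(x$meta$age, na.rm = TRUE),
                           max(x$meta$age, na.rm = TRUE))))
  invisible(x)
}

#' Cross-spectra tensor
#'
#' Complex subject x channel x channel x frequency cross-spectral matrices.
#' Every channel x channel slice must be Hermitian with a real, positive
#' diagonal.
#'
#' @param values complex (or numeric) 4-d array.
#' @param grid a [frequency_grid()].
#' @param channels electrode labels.
#' @param meta optional subject metadata (see [power_spectra()]).
#' @param tol Hermitian-symmetry tolerance relative to the largest modulus.
#' @return An object of class `"cross_spectra"`.
#' @export
cross_spectra <- function(values, grid, channels, meta = NULL, tol = 1e-8) {
  stopifnot(is.array(values), length(dim(values)) == 4L)
  if (!is_frequency_grid(grid)) stop("grid must be a frequency_grid")
  d <- dim(values)
  if (d[2L] != d[3L]) stop("channel dimensions must be square")
  channels <- as.character(channels)
  if (d[2L] != length(channels)) stop("channel labels must match dimension")
  if (d[4L] != grid$n_bins) stop("frequency dimension must match grid")
  if (!is.complex(values)) values <- values + 0i
  scl <- max(Mod(values), 1e-300)
  for (f in seq_len(d[4L])) {
    for (s in seq_len(d[1L])) {
      sl <- values[s, , , f]
      if (max(Mod(sl - Conj(t(sl)))) > tol * scl)
        stop("cross-spectral slice is not Hermitian")
    }
  }
  if (is.null(meta)) meta <- validate_meta(
    data.frame(subject_id = sprintf("S%03d", seq_len(d[1L]))), n = d[1L])
  else meta <- validate_meta(meta, n = d[1L])
  structure(list(values = values, grid = grid, channels = channels, meta = meta),
            class = "cross_spectra")
}

#' Extract power spectra from cross-spectra diagonals
#'
#' The power spectrum of each channel is the (real, nonnegative) diagonal of
#' the Hermitian cross-spectral matrix at each frequency.
#'
#' @param cross a [cross_spectra()] object.
#' @param tol maximum tolerated relative imaginary part on the diagonal.
#' @return A linear-scale [power_spectra()] object.
#' @export
diagonal_power <- function(cross, tol = 1e-8) {
  stopifnot(inherits(cross, "cross_spectra"))
  d <- dim(cross$values)
  n_ch <- d[2L]
  out <- array(NA_real_, dim = c(d[1L], n_ch, d[4L]))
  scl <- max(Mod(cross$values), 1e-300)
  for (c_i in seq_len(n_ch)) {
    diag_block <- cross$values[, c_i, c_i, , drop = FALSE]
    if (max(abs(Im(diag_block))) > tol * scl)
      stop("non-negligible imaginary part on cross-spectral diagonal")
    out[, c_i, ] <- Re(diag_block)
  }
  if (any(out <= 0)) stop("nonpositive power on cross-spectral diagonal")
  power_spectra(out, cross$grid, cross$channels, cross$meta, scale = "linear")
}

#' Average-reference cross-spectra and drop one electrode
#'
#' Re-references the cross-spectral matrices to the common average:
#' `S' = H S H` with `H = I - (1/n) 11'` applied per frequency over all `n`
#' channels, then removes the row/column of `drop`.  `H` is a rank-(n-1)
#' projector, so the referenced matrices are rank deficient by one; dropping
#' one electrode (conventionally Pz) restores a full-rank set.
#'
#' @param cross a [cross_spectra()] object.
#' @param drop electrode label to remove after referencing (default `"Pz"`).
#' @return A [cross_spectra()] object with `n - 1` channels.
#' @export
average_reference <- function(cross, drop = "Pz") {
  stopifnot(inherits(cross, "cross_spectra"))
  ch <- cross$channels
  if (!drop %in% ch) stop(sprintf("drop label '%s' not among channels", drop))
  n <- length(ch)
  if (n < 2L) stop("need at least 2 channels")
  H <- diag(n) - matrix(1 / n, n, n)
  keep <- which(ch != drop)
  d <- dim(cross$values)
  out <- array(0i, dim = c(d[1L], n - 1L, n - 1L, d[4L]))
  for (s in seq_len(d[1L])) {
    for (f in seq_len(d[4L])) {
      Sref <- H %*% cross$values[s, , , f] %*% H  # H symmetric: H S H'
      out[s, , , f] <- Sref[keep, keep]
    }
  }
  cross_spectra(out, cross$grid, ch[keep], cross$meta)
}

#' Remove per-subject global scale from log power spectra
#'
#' Subtracts each subject's mean log power over all channels and frequencies,
#' i.e. divides the linear spectra by their geometric mean.  This removes the
#' arbitrary global amplitude factor (amplifier gain, skull conductivity)
#' before spectra are compared across subjects.
#'
#' @param psd a log-scale [power_spectra()] object.
#' @return A log-scale [power_spectra()] object with per-subject mean zero.
#' @export
global_scale_correct <- function(psd) {
  stopifnot(inherits(psd, "power_spectra"))
  if (psd$scale != "log")
    stop("global scale correction expects log-scale spectra; use log_transform()")
  v <- psd$values
  subj_means <- apply(v, 1L, mean)
  v <- sweep(v, 1L, subj_means, "-")
  power_spectra(v, psd$grid, psd$channels, psd$meta, scale = "log")
}

#' Switch power spectra between linear and natural-log scale
#'
#' @param psd a [power_spectra()] object.
#' @return A [power_spectra()] object on the other scale.
#' @export
log_transform <- function(psd) {
  stopifnot(inherits(psd, "power_spectra"))
  if (psd$scale == "log") stop("spectra already on log scale")
  power_spectra(log(psd$values), psd$grid, psd$channels, psd$meta, scale = "log")
}

#' @rdname log_transform
#' @export
exp_transform <- function(psd) {
  stopifnot(inherits(psd, "power_spectra"))
  if (psd$scale == "linear") stop("spectra already on linear scale")
  power_spectra(exp(psd$values), psd$grid, psd$channels, psd$meta,
                scale = "linear")
}

#' Read / write power spectra in TSV long format
#'
#' The long format has one row per (subject, channel, frequency) cell with
#' columns `subject_id`, `channel`, `freq_hz`, `value`, UTF-8 encoded with
#' `.` as decimal separator.  Metadata travels in a companion TSV with
#' columns `subject_id`, `age`, `sex`, `site`.  Every subject must cover the
#' identical complete grid; a missing cell is an error, never an NA.
#'
#' @param path spectra TSV path.
#' @param meta_path optional metadata TSV path; for `write_spectra` written
#'   alongside when given.
#' @param scale power scale of the stored values.
#' @param format only `"tsv"` is supported.
#' @return `read_spectra()`: a [power_spectra()] object. `write_spectra()`:
#'   the input, invisibly.
#' @examples
#' ps <- make_cohort(cohort_config(n = 3, seed = 1))$spectra
#' f <- tempfile(fileext = ".tsv")
#' write_spectra(ps, f)
#' ps2 <- read_spectra(f, scale = "log")
#' all.equal(ps$values, ps2$values)
#' @export
read_spectra <- function(path, meta_path = NULL, scale = c("log", "linear"),
                         format = "tsv") {
  scale <- match.arg(scale)
  if (!identical(format, "tsv")) stop("only the TSV long format is supported")
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("subject_id", "channel", "freq_hz", "value")
  if (!all(need %in% names(tab)))
    stop("spectra TSV must have columns subject_id, channel, freq_hz, value")
  if (!is.numeric(tab$value) || !is.numeric(tab$freq_hz))
    stop("non-numeric power or frequency values")
  subjects <- unique(tab$subject_id)
  channels <- unique(tab$channel)
  freqs <- sort(unique(tab$freq_hz))
  n_f <- length(freqs)
  if (n_f < 2L) stop("need at least two frequency bins")
  steps <- diff(freqs)
  if (max(abs(steps - steps[1L])) > 1e-6 * steps[1L])
    stop("frequencies do not form a regular grid")
  grid <- frequency_grid(freqs[1L], mean(steps), n_f)
  n_s <- length(subjects); n_c <- length(channels)
  if (nrow(tab) != n_s * n_c * n_f)
    stop("incomplete grid: each subject must cover every (channel, freq) cell")
  si <- match(tab$subject_id, subjects)
  ci <- match(tab$channel, channels)
  fi <- findInterval(tab$freq_hz, freqs - grid$step_hz / 2)
  arr <- array(NA_real_, dim = c(n_s, n_c, n_f))
  arr[cbind(si, ci, fi)] <- tab$value
  if (anyNA(arr))
    stop("incomplete grid: duplicated and missing (subject, channel, freq) cells")
  meta <- NULL
  if (!is.null(meta_path)) {
    if (!file.exists(meta_path)) stop(sprintf("file not found: %s", meta_path))
    meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE, encoding = "UTF-8")
    meta <- validate_meta(meta)
    if (!setequal(meta$subject_id, subjects))
      stop("metadata subjects do not match spectra subjects")
    meta <- meta[match(subjects, meta$subject_id), , drop = FALSE]
  } else {
    meta <- validate_meta(data.frame(subject_id = subjects), n = n_s)
  }
  power_spectra(arr, grid, channels, meta, scale = scale)
}

#' @rdname read_spectra
#' @param psd a [power_spectra()] object to write.
#' @export
write_spectra <- function(psd, path, meta_path = NULL, format = "tsv") {
  stopifnot(inherits(psd, "power_spectra"))
  if (!identical(format, "tsv")) stop("only the TSV long format is supported")
  d <- dim(psd$values)
  tab <- data.frame(
    subject_id = rep(psd$meta$subject_id, times = d[2L] * d[3L]),
    channel = rep(rep(psd$channels, each = d[1L]), times = d[3L]),
    freq_hz = rep(psd$grid$freqs, each = d[1L] * d[2L]),
    value = as.vector(psd$values),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(meta_path))
    utils::write.table(psd$meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  invisible(psd)
}
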