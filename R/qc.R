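#' WHO-style age group labels
#'
#' Half-open upper-bin convention so every positive age is assignable:
#' minors (age <= 18), youth (18, 45], middle (45, 60], elderly (> 60).
#'
#' @param age numeric vector of ages in years.
#' @return Factor with levels minors, youth, middle, elderly.
#' @export
age_group <- function(age) {
  stopifnot(is.numeric(age), all(age > 0, na.rm = TRUE))
  cut(age, breaks = c(0, 18, 45, 60, Inf),
      labels = c("minors", "youth", "middle", "elderly"), right = TRUE)
}

#' Z-score flattened spectra for outlier screening
#'
#' Flattens the tensor to subject x (channel * frequency) and standardizes
#' every column to mean 0 and (population) SD 1, so a two-subject column
#' with values {0, 2} maps to {-1, +1}.
#'
#' @param psd a [power_spectra()] object.
#' @return Numeric matrix, subjects x features.
#' @export
zscore_features <- function(psd) {
  stopifnot(inherits(psd, "power_spectra"))
  d <- dim(psd$values)
  if (d[1L] < 2L) stop("need at least 2 subjects")
  X <- matrix(psd$values, nrow = d[1L])  # columns: channel-major then freq
  mus <- colMeans(X)
  sds <- sqrt(colMeans(sweep(X, 2L, mus, "-")^2))
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1L]
    ch <- ((bad - 1L) %% d[2L]) + 1L
    fr <- ((bad - 1L) %/% d[2L]) + 1L
    stop(sprintf("zero-variance column: channel %s, %.4g Hz",
                 psd$channels[ch], psd$grid$freqs[fr]))
  }
  sweep(sweep(X, 2L, mus, "-"), 2L, sds, "/")
}

#' Deterministic 2-D embedding of a feature matrix
#'
#' Projects subjects onto the first two principal components.  The sign of
#' each component is fixed (largest-magnitude loading positive) so the
#' embedding is fully deterministic and invariant to the BLAS in use; the
#' `seed` argument is accepted for interface stability with stochastic
#' embedders.
#'
#' @param X numeric matrix, subjects x features (>= 10 subjects).
#' @param seed integer; unused by the PCA embedding but recorded.
#' @return Numeric matrix, subjects x 2, with attribute `"seed"`.
#' @export
embed_2d <- function(X, seed = 1L) {
  stopifnot(is.matrix(X))
  if (nrow(X) < 10L)
    stop("need at least 10 subjects to embed; reduce neighborhood demands or pool groups")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = 2L)
  rot <- pc$rotation
  for (j in 1:2) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) rot[, j] <- -rot[, j]
  }
  emb <- scale(X, center = pc$center, scale = FALSE) %*% rot
  colnames(emb) <- c("dim1", "dim2")
  attr(emb, "seed") <- as.integer(seed)
  emb
}

#' Flag outliers by robust distance within age groups
#'
#' Within each age group, robust location and scatter of the 2-D embedding
#' coordinates are estimated by the minimum covariance determinant (MCD);
#' subjects whose squared robust Mahalanobis distance exceeds the
#' chi-square(df = 2) quantile at `quantile` are flagged.  Groups with fewer
#' than `min_group` members are skipped with a warning (no flags).  Rows are
#' canonically ordered before estimation so results are invariant to subject
#' permutation.
#'
#' @param coords subjects x 2 embedding matrix.
#' @param meta subject metadata with an `age` column (see [power_spectra()]).
#' @param quantile chi-square probability for the threshold (default 0.975).
#' @param seed integer seed for the MCD subset search.
#' @param min_group minimum group size (default 5).
#' @return A data frame of class `"qc_report"` with columns `subject_id`,
#'   `age`, `group`, `dim1`, `dim2`, `rd2` (squared robust distance),
#'   `threshold`, `outlier`.
#' @export
flag_outliers <- function(coords, meta, quantile = 0.975, seed = 1L,
                          min_group = 5L) {
  stopifnot(is.matrix(coords), ncol(coords) == 2L)
  meta <- validate_meta(meta, n = nrow(coords))
  if (any(is.na(meta$age))) stop("ages are required for grouped QC")
  stopifnot(quantile > 0, quantile <= 1)
  grp <- age_group(meta$age)
  thr <- stats::qchisq(quantile, df = 2L)
  rd2 <- rep(NA_real_, nrow(coords))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (!length(idx)) next
    if (length(idx) < min_group) {
      warning(sprintf("age group '%s' has %d subject(s); skipped", g,
                      length(idx)))
      next
    }
    pts <- coords[idx, , drop = FALSE]
    ord <- order(pts[, 1L], pts[, 2L])     # canonical order: permutation-proof
    est <- withr_seed(seed, MASS::cov.rob(pts[ord, , drop = FALSE],
                                          method = "mcd"))
    if (min(eigen(est$cov, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop(sprintf("degenerate robust scatter in age group '%s'", g))
    rd2[idx] <- stats::mahalanobis(pts, est$center, est$cov)
  }
  out <- data.frame(subject_id = meta$subject_id, age = meta$age,
                    group = as.character(grp),
                    dim1 = coords[, 1L], dim2 = coords[, 2L],
                    rd2 = rd2, threshold = thr,
                    outlier = !is.na(rd2) & rd2 > thr,
                    stringsAsFactors = FALSE)
  class(out) <- c("qc_report", "data.frame")
  out
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d subjects, %d flagged (threshold %.4f)\n",
              nrow(x), sum(x$outlier), x$threshold[1L]))
  print(table(group = x$group, outlier = x$outlier))
  invisible(x)
}

#' One-call cohort QC
#'
#' Convenience wrapper: z-score the spectra, embed in 2-D and flag outliers
#' per age group.
#'
#' @param psd a [power_spectra()] object with ages in its metadata.
#' @inheritParams flag_outliers
#' @return A `"qc_report"` data frame (see [flag_outliers()]).
#' @export
qc_cohort <- function(psd, quantile = 0.975, seed = 1L, min_group = 5L) {
  X <- zscore_features(psd)
  emb <- embed_2d(X, seed = seed)
  flag_outliers(emb, psd$meta, quantile = quantile, seed = seed,
                min_group = min_group)
}
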