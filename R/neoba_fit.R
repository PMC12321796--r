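#' Fit the oscillation-based brain-age model to a cohort
#'
#' End-to-end fit: (optional) QC flagging and exclusion, per-channel
#' spectral decomposition, the 13 electrode-wise oscillatory features,
#' per-subject sparse-group-lasso dependency (ODC) matrices, and 10-fold
#' cross-validated age regression with the Levenberg-Marquardt-trained
#' fully connected network.  A final network is also trained on the full
#' cohort for [predict.neoba_fit()] and relevance analysis.
#'
#' @param spectra a log- or linear-scale [power_spectra()] object with ages
#'   in its metadata.
#' @param mode input layout: `"fused"` (OSF + ODC, 390 dims on the default
#'   montage), `"osf"` (234) or `"odc"` (156).
#' @param lambda1,lambda2 sparse-group-lasso penalties (defaults 2^-6 and
#'   0.1).
#' @param k cross-validation folds.
#' @param seed integer seed governing QC, folds and network training.
#' @param qc run outlier screening and drop flagged subjects first.
#' @param scale_correct apply per-subject global scale correction.
#' @param config a [spec_config()] for the spectral decomposition.
#' @param ... further arguments to [train_lm()] (e.g. `max_epochs`).
#' @return An object of class `"neoba_fit"` with elements `cv`
#'   ([kfold_cv()] result), `network` (full-data `"net_params"`), `scaler`,
#'   `osf`, `odc`, `input` ([assemble_input()] result), `importance`
#'   ([pcc_importance()]), `qc` (report or NULL), `meta`, `mode`, `lambdas`,
#'   `seed`.
#' @examples
#' \donttest{
#' cohort <- make_cohort(cohort_config(n = 60, seed = 1))
#' fit <- neoba_fit(cohort$spectra, mode = "osf", k = 5, max_epochs = 15)
#' fit
#' }
#' @export
neoba_fit <- function(spectra, mode = c("fused", "osf", "odc"),
                      lambda1 = 2^-6, lambda2 = 0.1, k = 10L, seed = 1L,
                      qc = FALSE, scale_correct = TRUE,
                      config = spec_config(), ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(spectra, "power_spectra"))
  if (spectra$scale != "log") spectra <- log_transform(spectra)
  if (any(is.na(spectra$meta$age))) stop("ages are required to fit")
  qc_report <- NULL
  if (qc) {
    qc_report <- qc_cohort(spectra, seed = seed)
    keep <- !qc_report$outlier
    spectra <- power_spectra(spectra$values[keep, , , drop = FALSE],
                             spectra$grid, spectra$channels,
                             spectra$meta[keep, , drop = FALSE],
                             scale = "log")
  }
  if (scale_correct) spectra <- global_scale_correct(spectra)
  models <- fit_cohort_spectra(spectra, config)
  osf <- build_osf_table(models, spectra)
  odc <- if (mode %in% c("fused", "odc"))
    odc_cohort(osf, lambda1, lambda2) else NULL
  input <- assemble_input(osf, odc, mode = mode)
  ages <- spectra$meta$age
  cv <- kfold_cv(input$matrix, ages, k = k, seed = seed, ...)
  scaler <- fit_scaler(input$matrix)
  network <- train_lm(apply_scaler(input$matrix, scaler), ages,
                      seed = seed, ...)
  structure(list(cv = cv, network = network, scaler = scaler, osf = osf,
                 odc = odc, input = input,
                 importance = pcc_importance(osf, ages), qc = qc_report,
                 meta = spectra$meta, mode = mode,
                 lambdas = c(lambda1 = lambda1, lambda2 = lambda2),
                 seed = seed),
            class = "neoba_fit")
}

#' @export
print.neoba_fit <- function(x, ...) {
  cat(sprintf("Brain-age model (%s input, %d features, %d subjects)\n",
              x$mode, ncol(x$input$matrix), nrow(x$input$matrix)))
  print(x$cv)
  invisible(x)
}

#' @export
summary.neoba_fit <- function(object, ...) {
  cat(sprintf("Brain-age model -- %s input, %d subjects, seed %d\n",
              object$mode, nrow(object$input$matrix), object$seed))
  if (object$mode != "osf")
    cat(sprintf("  SGL penalties: lambda1 = %g, lambda2 = %g\n",
                object$lambdas["lambda1"], object$lambdas["lambda2"]))
  print(object$cv)
  cat("Per-fold MAE (years):\n")
  print(round(object$cv$per_fold[, "mae"], 2))
  cat("Region-level feature-age correlations:\n")
  print(round(object$importance$region_pcc, 2))
  invisible(object)
}

#' @export
#' @rdname neoba_fit
#' @param object a fitted `"neoba_fit"`.
#' @param newdata a [power_spectra()] object, or a raw input matrix matching
#'   the fitted layout.  Defaults to the training input.
predict.neoba_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    X <- object$input$matrix
  } else if (inherits(newdata, "power_spectra")) {
    sp <- if (newdata$scale != "log") log_transform(newdata) else newdata
    sp <- global_scale_correct(sp)
    models <- fit_cohort_spectra(sp)
    osf <- build_osf_table(models, sp)
    odc <- if (object$mode %in% c("fused", "odc"))
      odc_cohort(osf, object$lambdas["lambda1"], object$lambdas["lambda2"])
    else NULL
    X <- assemble_input(osf, odc, mode = object$mode)$matrix
  } else {
    X <- as.matrix(newdata)
  }
  predict.net_params(object$network, apply_scaler(X, object$scaler))
}

#' @export
residuals.neoba_fit <- function(object, ...) {
  with(object$cv$predictions, yhat - y)  # brain-age gap, out-of-fold
}

#' @export
plot.neoba_fit <- function(x, y, ...) {
  p <- x$cv$predictions
  plot(p$y, p$yhat, pch = 16, cex = 0.6, xlab = "Chronological age (y)",
       ylab = "Predicted age (y)", ...)
  abline(0, 1, col = "firebrick")
  invisible(x)
}

#' Relevance analysis of a fitted model
#'
#' Cohort-averaged layerwise relevance propagation over the fitted input.
#'
#' @param fit a [neoba_fit()] result.
#' @param mode `"sum"` or `"mean"` group pooling.
#' @param ... options for [lrp_backward()].
#' @return A `"group_relevance"` object.
#' @export
relevance <- function(fit, mode = "sum", ...) {
  stopifnot(inherits(fit, "neoba_fit"))
  Xs <- apply_scaler(fit$input$matrix, fit$scaler)
  cohort_relevance(fit$network, Xs, fit$input$layout, mode = mode, ...)
}
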