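#' Layerwise relevance propagation through the trained network
#'
#' Starting from an output relevance of 1, relevance is propagated backward
#' layer by layer with the signed-decomposition rule: each upstream neuron's
#' contribution is split into a positive-weight part normalized by the total
#' positive pre-activation (plus the positive bias part) and a
#' negative-weight part normalized by the total negative pre-activation
#' (plus the negative bias part); denominators are stabilized by
#' `eps * sign(denominator)`.  By default the two branch contributions of
#' each downstream neuron are renormalized to sum to 1, which makes the
#' decomposition conserving (layer totals match) in the bias-free case and
#' reduces exactly to plain proportional attribution when all contributions
#' are nonnegative; `renormalize = FALSE` applies the raw two-branch rule.
#'
#' @param params a `"net_params"` object (see [train_lm()]).
#' @param x a single input vector on the network's input scale.
#' @param eps denominator stabilizer (default 1e-9).
#' @param renormalize renormalize per downstream neuron (default TRUE).
#' @param literal_bias use the unsigned bias in the negative-branch
#'   denominator instead of its negative part.
#' @param stop_at layer index to stop at: 0 (default) propagates to the
#'   input layer; 1 stops at the first hidden layer's activations.
#' @return List of class `"relevance_map"`: `input` (relevance per input
#'   dimension, when `stop_at = 0`), `layers` (relevance vectors per layer,
#'   outermost first), `total` per layer.
#' @export
lrp_backward <- function(params, x, eps = 1e-9, renormalize = TRUE,
                         literal_bias = FALSE, stop_at = 0L) {
  stopifnot(inherits(params, "net_params"))
  A <- fcnn_forward(params, matrix(x, nrow = 1L))
  if (!all(vapply(A, function(a) all(is.finite(a)), logical(1))))
    stop("non-finite activation")
  L <- length(params$W)
  stabil <- function(d) d + eps * ifelse(d >= 0, 1, -1)
  R <- list()
  R[[L + 1L]] <- 1   # output relevance
  lowest <- max(stop_at + 1L, 1L)
  for (l in rev(seq_len(L))) {
    if (l < lowest) break
    a <- as.numeric(A[[l]])
    W <- params$W[[l]]; b <- params$b[[l]]
    Rk <- R[[l + 1L]]
    z <- a * W                      # contributions a_i * w_ik, p_in x p_out
    zp <- pmax(z, 0); zn <- pmin(z, 0)
    bp <- pmax(b, 0)
    bn <- if (literal_bias) b else pmin(b, 0)
    denp <- stabil(colSums(zp) + bp)
    denn <- stabil(colSums(zn) + bn)
    C <- sweep(zp, 2L, denp, "/") + sweep(zn, 2L, denn, "/")
    if (renormalize) {
      tot <- colSums(C)
      tot <- ifelse(abs(tot) > eps, tot, stabil(tot))
      C <- sweep(C, 2L, tot, "/")
    }
    R[[l]] <- as.numeric(C %*% Rk)
  }
  layers <- R[!vapply(R, is.null, logical(1))]
  structure(list(input = if (stop_at == 0L) R[[1L]] else NULL,
                 layers = rev(layers),
                 total = vapply(rev(layers), sum, numeric(1)),
                 stop_at = stop_at),
            class = "relevance_map")
}

#' Aggregate input relevance by feature group and electrode
#'
#' Maps the input relevance vector back onto the feature layout: the OSF
#' block is reshaped to electrode x feature and pooled per feature group
#' (AP, PP, PR, RP); the ODC block is pooled as one group.  `"sum"` mode
#' preserves totals (group values sum to the total input relevance);
#' `"mean"` mode averages over group members.
#'
#' @param rmap a [lrp_backward()] result with input relevances.
#' @param layout the `layout` data frame from [assemble_input()].
#' @param mode `"sum"` or `"mean"`.
#' @param absolute pool absolute relevances instead of signed ones.
#' @return List of class `"group_relevance"`: `groups` (named vector),
#'   `electrode_feature` (electrode x feature matrix, OSF block), `mode`.
#' @export
aggregate_relevance <- function(rmap, layout, mode = c("sum", "mean"),
                                absolute = FALSE) {
  mode <- match.arg(mode)
  r <- if (inherits(rmap, "relevance_map")) rmap$input else as.numeric(rmap)
  if (is.null(r)) stop("relevance map does not reach the input layer")
  if (length(r) != nrow(layout)) stop("relevance length does not match layout")
  if (absolute) r <- abs(r)
  pool <- if (mode == "sum") sum else mean
  groups <- tapply(r, factor(layout$group, levels = unique(layout$group)), pool)
  groups <- stats::setNames(as.numeric(groups), names(groups))
  ef <- NULL
  osf_rows <- layout$block == "osf" & !is.na(layout$electrode) &
    !is.na(layout$feature)
  if (any(osf_rows)) {
    sub <- layout[osf_rows, ]
    electrodes <- unique(sub$electrode)
    feats <- unique(sub$feature)
    ef <- matrix(r[osf_rows][order(match(sub$feature, feats),
                                   match(sub$electrode, electrodes))],
                 nrow = length(electrodes),
                 dimnames = list(electrodes, feats))
  }
  structure(list(groups = groups, electrode_feature = ef, mode = mode),
            class = "group_relevance")
}

#' @export
print.group_relevance <- function(x, ...) {
  cat(sprintf("Group relevance (%s mode):\n", x$mode))
  print(round(x$groups, 4))
  invisible(x)
}

#' Cohort-averaged relevance
#'
#' Runs [lrp_backward()] for every subject, averages the per-subject input
#' relevance maps and renormalizes the average to sum to 1 before group
#' aggregation.
#'
#' @param params a trained `"net_params"`.
#' @param X subjects x input matrix on the network's input scale.
#' @param layout the input layout from [assemble_input()].
#' @param mode,absolute see [aggregate_relevance()].
#' @param ... further options for [lrp_backward()].
#' @return A `"group_relevance"` object with the averaged, renormalized
#'   input relevance in `$input`.
#' @export
cohort_relevance <- function(params, X, layout, mode = "sum",
                             absolute = FALSE, ...) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty cohort")
  acc <- numeric(nrow(layout))
  for (s in seq_len(nrow(X)))
    acc <- acc + lrp_backward(params, X[s, ], ...)$input
  avg <- acc / nrow(X)
  tot <- sum(avg)
  if (abs(tot) > 1e-12) avg <- avg / tot
  out <- aggregate_relevance(avg, layout, mode = mode, absolute = absolute)
  out$input <- avg
  out
}
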