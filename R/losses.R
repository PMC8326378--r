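#' Loss weights of the composite multi-task loss
#'
#' The composite loss is \code{w1 * Loss1 + w2 * Loss2}, where
#' \code{Loss1} is the multi-label binary cross-entropy over keypoint
#' presence and \code{Loss2} the masked log-cosh coordinate loss.
#' Because the log-cosh term is much smaller than the cross-entropy
#' term, the regression weight defaults to 10 against 1 to keep the two
#' tasks balanced.
#'
#' @param w1 Classification weight (>= 0, default 1).
#' @param w2 Regression weight (>= 0, default 10).
#' @return List with class \code{"loss_weights"}.
#' @export
loss_weights <- function(w1 = 1, w2 = 10) {
  stopifnot(w1 >= 0, w2 >= 0)
  if (w1 == 0 && w2 == 0) stop("loss weights must not both be zero")
  structure(list(w1 = w1, w2 = w2), class = "loss_weights")
}

#' Multi-label binary cross-entropy
#'
#' Mean over the keypoint classes (and the batch) of
#' \code{-[y log p + (1 - y) log(1 - p)]}, with probabilities clipped
#' to \code{[eps, 1 - eps]} before the logarithm.
#'
#' @param presence Binary vector or (batch x classes) matrix of
#'   ground-truth presence.
#' @param probabilities Predicted probabilities, same shape.
#' @param eps Clipping constant (default 1e-7).
#' @return Non-negative scalar.
#' @export
classification_loss <- function(presence, probabilities, eps = 1e-7) {
  if (length(presence) != length(probabilities)) {
    stop("presence and probabilities must have equal length")
  }
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  -mean(presence * log(p) + (1 - presence) * log(1 - p))
}

#' Masked log-cosh regression loss
#'
#' Mean over the masked-in coordinate entries of
#' \code{log(cosh(pred - true))}, evaluated in the numerically stable
#' form \code{|e| + log1p(exp(-2|e|)) - log 2} (no overflow for any
#' error magnitude). Entries with mask 0 — absent keypoints — contribute
#' nothing: there is no ground truth to regress toward.
#'
#' @param coords_true,coords_pred Equal-length numeric vectors (or
#'   matrices).
#' @param mask Binary vector of the same length; \code{NULL} means all
#'   entries count.
#' @return Non-negative scalar; 0 when no entry is masked in.
#' @export
log_cosh_loss <- function(coords_true, coords_pred, mask = NULL) {
  if (length(coords_true) != length(coords_pred)) {
    stop("coordinate vectors must have equal length")
  }
  if (is.null(mask)) mask <- rep(1, length(coords_true))
  if (length(mask) != length(coords_true)) {
    stop("mask must match the coordinate length")
  }
  n <- sum(mask)
  if (n == 0) return(0)
  e <- abs(coords_pred - coords_true)
  v <- e + log1p(exp(-2 * e)) - log(2)
  sum(v * mask) / n
}

# Per-element log-cosh, stable for any |e| (used by tests and docs).
log_cosh <- function(e) {
  e <- abs(e)
  e + log1p(exp(-2 * e)) - log(2)
}

#' Composite multi-task loss
#'
#' \code{total = w1 * loss1 + w2 * loss2} with \code{loss1} the
#' classification cross-entropy and \code{loss2} the masked log-cosh
#' term.
#'
#' @param target A \code{target_encoding} (or list of them /
#'   batch matrices \code{presence}, \code{coords}, \code{mask}).
#' @param pred A prediction bundle with \code{probabilities} and
#'   \code{coords} (vectors or batch matrices).
#' @param weights A \code{\link{loss_weights}}.
#' @param eps Probability clipping constant.
#' @return List with class \code{"loss_report"}: \code{loss1},
#'   \code{loss2}, \code{total}.
#' @export
composite_loss <- function(target, pred, weights = loss_weights(),
                           eps = 1e-7) {
  l1 <- classification_loss(target$presence, pred$probabilities, eps)
  l2 <- log_cosh_loss(target$coords, pred$coords, target$mask)
  structure(list(loss1 = l1, loss2 = l2,
                 total = weights$w1 * l1 + weights$w2 * l2),
            class = "loss_report")
}

# Gradients of the composite loss w.r.t. classifier logits and
# regressor outputs for a batch (matrices N x 11, N x 22). Masked
# coordinate slots receive exactly zero gradient.
composite_loss_grad <- function(presence, mask, probs, coords_true, coords,
                                weights) {
  n_cls <- length(probs)
  dlogits <- weights$w1 * (probs - presence) / n_cls
  n_mask <- sum(mask)
  dcoords <- if (n_mask > 0) {
    weights$w2 * tanh(coords - coords_true) * mask / n_mask
  } else {
    array(0, dim = dim(coords))
  }
  list(dlogits = dlogits, dcoords = dcoords)
}
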