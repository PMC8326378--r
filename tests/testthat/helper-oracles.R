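# Independent scalar oracles and small fixture builders used across
# the suite. The oracles deliberately loop over frames and classes one
# element at a time so they share no code path with the package's
# vectorized implementations.

oracle_confusion <- function(Y, P, thr = 0.5) {
  K <- ncol(Y)
  tp <- fp <- fn <- tn <- integer(K)
  for (i in seq_len(nrow(Y))) {
    for (k in seq_len(K)) {
      truth <- Y[i, k] >= 0.5
      pred <- P[i, k] >= thr
      if (pred && truth) tp[k] <- tp[k] + 1L
      else if (pred && !truth) fp[k] <- fp[k] + 1L
      else if (!pred && truth) fn[k] <- fn[k] + 1L
      else tn[k] <- tn[k] + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_metrics <- function(cc) {
  TP <- sum(cc$tp); FP <- sum(cc$fp); FN <- sum(cc$fn); TN <- sum(cc$tn)
  prec <- if (TP + FP > 0) TP / (TP + FP) else 0
  rec <- if (TP + FN > 0) TP / (TP + FN) else 0
  micro <- if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else 0
  acc <- (TP + TN) / (TP + FP + FN + TN)
  f1 <- num <- den <- 0
  for (k in seq_along(cc$tp)) {
    f1k <- if (2 * cc$tp[k] + cc$fp[k] + cc$fn[k] > 0) {
      2 * cc$tp[k] / (2 * cc$tp[k] + cc$fp[k] + cc$fn[k])
    } else 0
    sup <- cc$tp[k] + cc$fn[k]
    num <- num + f1k * sup
    den <- den + sup
  }
  macro <- if (den > 0) num / den else 0
  list(precision = prec, recall = rec, micro_f1 = micro, macro_f1 = macro,
       accuracy = acc)
}

oracle_regression <- function(Yt, Yp, M) {
  errs <- c()
  for (i in seq_len(nrow(Yt))) {
    for (j in seq_len(ncol(Yt))) {
      if (M[i, j] >= 0.5) errs <- c(errs, Yp[i, j] - Yt[i, j])
    }
  }
  c(mae = mean(abs(errs)), mse = mean(errs^2), rmse = sqrt(mean(errs^2)))
}

# A tiny deterministic frame with a given keypoint subset.
make_frame <- function(labels, xs = NULL, ys = NULL, image = NULL,
                       stage = "positioning", contrast_on = FALSE,
                       frame_index = 0L) {
  n <- length(labels)
  if (is.null(xs)) xs <- seq(0.2, 0.8, length.out = n)
  if (is.null(ys)) ys <- seq(0.3, 0.7, length.out = n)
  annotated_frame(image = image,
                  keypoints = data.frame(label = labels, x = xs, y = ys),
                  stage = stage, contrast_on = contrast_on,
                  frame_index = frame_index)
}

# Random target/prediction batches for metric fuzzing.
random_batch <- function(n_frames, n_classes = 11L) {
  Y <- matrix(rbinom(n_frames * n_classes, 1, runif(1, 0.2, 0.8)),
              n_frames, n_classes)
  P <- matrix(runif(n_frames * n_classes), n_frames, n_classes)
  M <- t(apply(Y, 1, function(r) rep(r, each = 2)))
  Ct <- matrix(runif(n_frames * 2 * n_classes), n_frames, 2 * n_classes) * M
  Cp <- matrix(runif(n_frames * 2 * n_classes), n_frames, 2 * n_classes)
  list(Y = Y, P = P, M = M, Ct = Ct, Cp = Cp)
}

# Wrap matrices as encoding/bundle lists.
as_targets <- function(b) {
  lapply(seq_len(nrow(b$Y)), function(i) {
    structure(list(presence = b$Y[i, ], coords = b$Ct[i, ], mask = b$M[i, ]),
              class = "target_encoding")
  })
}

as_preds <- function(b) {
  structure(list(probabilities = b$P, coords = b$Cp), class = "mtk_pred")
}

small_phantom <- function(n = 20L, seed = 11L, image_size = 64L,
                          render = TRUE, ...) {
  generate_phantom(phantom_config(n_frames = n, image_size = image_size,
                                  seed = seed, ...), render = render)
}
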