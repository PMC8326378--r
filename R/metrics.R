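#' Per-class confusion counts for multi-label presence prediction
#'
#' A keypoint is predicted present when its probability is at least the
#' threshold; counts are accumulated per class over the evaluated
#' frames, so \code{TP + FP + FN + TN} equals the number of frames for
#' every class.
#'
#' @param targets List of \code{target_encoding}s (or an N x 11
#'   presence matrix).
#' @param preds An \code{mtk_pred}, list of prediction bundles, or an
#'   N x 11 probability matrix.
#' @param threshold Presence threshold in (0, 1), default 0.5.
#' @return List with class \code{"confusion_counts"}: integer vectors
#'   \code{tp}, \code{fp}, \code{fn}, \code{tn} named by label, plus
#'   \code{n_frames}.
#' @export
confusion_counts <- function(targets, preds, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  Y <- .presence_matrix(targets)
  P <- .prob_matrix(preds)
  if (!all(dim(Y) == dim(P))) stop("targets and predictions differ in shape")
  pred <- P >= threshold
  truth <- Y >= 0.5
  tp <- colSums(pred & truth)
  fp <- colSums(pred & !truth)
  fn <- colSums(!pred & truth)
  tn <- colSums(!pred & !truth)
  labels <- if (ncol(Y) == 11L) kp_labels() else paste0("k", seq_len(ncol(Y)))
  structure(list(tp = stats::setNames(as.integer(tp), labels),
                 fp = stats::setNames(as.integer(fp), labels),
                 fn = stats::setNames(as.integer(fn), labels),
                 tn = stats::setNames(as.integer(tn), labels),
                 n_frames = nrow(Y)),
            class = "confusion_counts")
}

.presence_matrix <- function(targets) {
  if (is.matrix(targets)) return(targets)
  do.call(rbind, lapply(targets, function(t) t$presence))
}

.prob_matrix <- function(preds) {
  if (is.matrix(preds)) return(preds)
  if (inherits(preds, "mtk_pred")) return(preds$probabilities)
  do.call(rbind, lapply(preds, function(p) p$probabilities))
}

.coord_matrix <- function(x, what = "coords") {
  if (is.matrix(x)) return(x)
  if (inherits(x, "mtk_pred")) return(x$coords)
  do.call(rbind, lapply(x, function(t) t[[what]]))
}

.f1_of <- function(tp, fp, fn) {
  den <- 2 * tp + fp + fn
  ifelse(den == 0, 0, 2 * tp / den)
}

#' Aggregated classification metrics
#'
#' Micro-averaged precision, recall, F1 and accuracy are computed by
#' applying the standard formulas to the counts pooled across classes;
#' the macro F1 is the support-weighted average of the per-class F1
#' scores (weights are the per-class positive counts). All 0/0 cases
#' resolve to 0.
#'
#' @param counts A \code{\link{confusion_counts}}.
#' @param macro Either \code{"weighted"} (default) or
#'   \code{"unweighted"}.
#' @return List: \code{precision}, \code{recall}, \code{micro_f1},
#'   \code{macro_f1}, \code{accuracy}, and a \code{per_class} data
#'   frame (label, precision, recall, f1, support).
#' @export
classification_metrics <- function(counts, macro = c("weighted", "unweighted")) {
  stopifnot(inherits(counts, "confusion_counts"))
  macro <- match.arg(macro)
  tp <- sum(counts$tp); fp <- sum(counts$fp)
  fn <- sum(counts$fn); tn <- sum(counts$tn)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  micro_f1 <- .f1_of(tp, fp, fn)
  accuracy <- if (tp + fp + fn + tn == 0) 0 else (tp + tn) / (tp + fp + fn + tn)
  pc_prec <- ifelse(counts$tp + counts$fp == 0, 0,
                    counts$tp / (counts$tp + counts$fp))
  pc_rec <- ifelse(counts$tp + counts$fn == 0, 0,
                   counts$tp / (counts$tp + counts$fn))
  pc_f1 <- .f1_of(counts$tp, counts$fp, counts$fn)
  support <- counts$tp + counts$fn
  macro_f1 <- if (macro == "weighted") {
    if (sum(support) == 0) 0 else sum(pc_f1 * support) / sum(support)
  } else {
    mean(pc_f1)
  }
  list(precision = precision, recall = recall, micro_f1 = micro_f1,
       macro_f1 = macro_f1, accuracy = accuracy,
       per_class = data.frame(label = names(counts$tp),
                              precision = unname(pc_prec),
                              recall = unname(pc_rec),
                              f1 = unname(pc_f1),
                              support = unname(as.integer(support)),
                              row.names = NULL))
}

#' Masked regression errors
#'
#' MAE, MSE and RMSE over the masked-in coordinate entries only,
#' pooled across the evaluation set (absent keypoints never enter).
#'
#' @param targets List of \code{target_encoding}s (or matrices
#'   \code{coords}/\code{mask}).
#' @param preds An \code{mtk_pred} / list of bundles / coordinate
#'   matrix.
#' @param mask Optional mask matrix when \code{targets} is a matrix.
#' @return Named vector \code{c(mae, mse, rmse)}.
#' @export
regression_metrics <- function(targets, preds, mask = NULL) {
  Yt <- .coord_matrix(targets, "coords")
  Yp <- .coord_matrix(preds)
  if (!all(dim(Yt) == dim(Yp))) stop("targets and predictions differ in shape")
  M <- if (!is.null(mask)) mask else .coord_matrix(targets, "mask")
  keep <- M >= 0.5
  n <- sum(keep)
  if (n == 0) stop("no masked-in coordinate entries to evaluate")
  e <- (Yp - Yt)[keep]
  mae <- mean(abs(e))
  mse <- mean(e^2)
  c(mae = mae, mse = mse, rmse = sqrt(mse))
}

#' Convert a normalized MAE into a pixel distance
#'
#' @param mae_normalized Mean absolute coordinate error in normalized
#'   units.
#' @param image_size Image side length in pixels.
#' @return \code{mae_normalized * image_size}.
#' @export
pixel_error <- function(mae_normalized, image_size) {
  if (mae_normalized < 0) stop("mae_normalized must be >= 0")
  if (image_size <= 0) stop("image_size must be positive")
  mae_normalized * image_size
}

#' Full evaluation report
#'
#' Classification and regression metrics of a prediction set against
#' its targets.
#'
#' @param targets List of \code{target_encoding}s.
#' @param preds An \code{mtk_pred} or list of bundles.
#' @param threshold Presence threshold.
#' @param macro Macro-F1 averaging mode.
#' @return List with class \code{"metrics_report"}.
#' @export
metrics_report <- function(targets, preds, threshold = 0.5,
                           macro = "weighted") {
  counts <- confusion_counts(targets, preds, threshold)
  cls <- classification_metrics(counts, macro)
  reg <- regression_metrics(targets, preds)
  structure(c(cls[c("precision", "recall", "macro_f1", "micro_f1",
                    "accuracy")],
              as.list(reg), list(per_class = cls$per_class,
                                 counts = counts)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("Classification: precision", round(x$precision, digits),
      " recall", round(x$recall, digits),
      " micro-F1", round(x$micro_f1, digits),
      " macro-F1", round(x$macro_f1, digits),
      " accuracy", round(x$accuracy, digits), "\n")
  cat("Regression (masked): MAE", round(x$mae, digits),
      " MSE", round(x$mse, digits),
      " RMSE", round(x$rmse, digits), "\n")
  invisible(x)
}

#' Write train/valid metric reports as a comparison CSV
#'
#' One row per metric with train and valid columns.
#'
#' @param reports Named list, e.g.
#'   \code{list(train = <metrics_report>, valid = <metrics_report>)}.
#' @param path Output CSV path.
#' @param model Model name recorded in the first column.
#' @return Invisibly, the data frame written.
#' @export
write_metrics_csv <- function(reports, path, model = "tiny_cnn") {
  metric_names <- c("precision", "recall", "macro_f1", "micro_f1",
                    "accuracy", "mae", "mse", "rmse")
  df <- data.frame(model = model, metric = metric_names)
  for (nm in names(reports)) {
    df[[nm]] <- vapply(metric_names, function(m) reports[[nm]][[m]],
                       numeric(1))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
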