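#' Training configuration
#'
#' Optimizer, batching and early-stopping settings. The original
#' clinical protocol (enabled with \code{paper_scale = TRUE}) is
#' Rectified Adam at learning rate 0.00001 with batch size 64 and up
#' to 100 epochs. The desk-scale defaults target the small
#' \code{tiny_cnn} trained from scratch on phantom data on one CPU:
#' learning rate 0.001, batch size 16, up to 60 epochs. Early stopping
#' (minimum improvement 0.005 over a patience of 5 epochs on the
#' validation composite loss) is shared by both scales.
#'
#' @param learning_rate Positive step size; \code{NULL} picks the
#'   scale default.
#' @param batch_size Positive frames per step; \code{NULL} picks the
#'   scale default.
#' @param max_epochs Epoch budget; \code{NULL} picks the scale
#'   default.
#' @param es_min_delta Minimum decrease of the monitored validation
#'   loss counted as an improvement.
#' @param es_patience Epochs without such an improvement before
#'   stopping (>= 1).
#' @param optimizer \code{"rectified_adam"} (default) or
#'   \code{"adam"}.
#' @param seed Seed controlling initialization and epoch shuffles.
#' @param weights A \code{\link{loss_weights}}.
#' @param paper_scale Use the clinical-protocol defaults.
#' @return List with class \code{"training_config"}.
#' @export
training_config <- function(learning_rate = NULL, batch_size = NULL,
                            max_epochs = NULL, es_min_delta = 0.005,
                            es_patience = 5L,
                            optimizer = c("rectified_adam", "adam"),
                            seed = 42L, weights = loss_weights(),
                            paper_scale = FALSE) {
  optimizer <- match.arg(optimizer)
  if (is.null(learning_rate)) learning_rate <- if (paper_scale) 1e-5 else 1e-3
  if (is.null(batch_size)) batch_size <- if (paper_scale) 64L else 16L
  if (is.null(max_epochs)) max_epochs <- if (paper_scale) 100L else 60L
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            es_min_delta > 0, es_patience >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 es_min_delta = es_min_delta,
                 es_patience = as.integer(es_patience),
                 optimizer = optimizer, seed = as.integer(seed),
                 weights = weights, paper_scale = isTRUE(paper_scale)),
            class = "training_config")
}

#' Early-stopping decision
#'
#' Running-best semantics: an epoch improves when its validation loss
#' undercuts the best seen so far by at least \code{min_delta} (the
#' best is then reset). Training stops once \code{patience}
#' consecutive epochs have passed without such an improvement.
#'
#' @param valid_history Non-empty numeric vector of per-epoch
#'   validation losses.
#' @param min_delta Minimum qualifying improvement.
#' @param patience Number of non-improving epochs tolerated.
#' @return \code{TRUE} if training should stop after the last recorded
#'   epoch.
#' @export
should_stop <- function(valid_history, min_delta = 0.005, patience = 5L) {
  if (length(valid_history) == 0L) stop("validation history is empty")
  best <- Inf
  wait <- 0L
  for (v in valid_history) {
    if (v < best - min_delta) {
      best <- v
      wait <- 0L
    } else {
      wait <- wait + 1L
    }
    if (wait >= patience) return(TRUE)
  }
  FALSE
}

# Encode a list of frames into batch tensors once.
.encode_set <- function(frames, spec) {
  enc <- lapply(frames, encode_targets)
  list(X = preprocess_batch(frames, spec),
       presence = do.call(rbind, lapply(enc, `[[`, "presence")),
       coords = do.call(rbind, lapply(enc, `[[`, "coords")),
       mask = do.call(rbind, lapply(enc, `[[`, "mask")),
       encodings = enc)
}

# Composite loss of a model over a pre-encoded set, in chunks.
.set_loss <- function(model, set, weights, chunk = 64L) {
  n <- nrow(set$presence)
  l1_sum <- 0; l2_num <- 0; l2_den <- 0
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    fw <- forward_model(model, set$X[, , , i:j, drop = FALSE])
    l1_sum <- l1_sum + classification_loss(set$presence[i:j, , drop = FALSE],
                                           fw$probs) * (j - i + 1L)
    m <- set$mask[i:j, , drop = FALSE]
    e <- abs(fw$coords - set$coords[i:j, , drop = FALSE])
    l2_num <- l2_num + sum((e + log1p(exp(-2 * e)) - log(2)) * m)
    l2_den <- l2_den + sum(m)
    i <- j + 1L
  }
  l1 <- l1_sum / n
  l2 <- if (l2_den > 0) l2_num / l2_den else 0
  list(loss1 = l1, loss2 = l2, total = weights$w1 * l1 + weights$w2 * l2)
}

#' Fit the multi-task keypoint model
#'
#' The package's central fitting routine: batched optimization of the
#' composite loss (weighted binary cross-entropy for presence +
#' masked log-cosh for coordinates) with per-epoch validation, early
#' stopping on the validation composite loss, and restoration of the
#' best-epoch parameters. With a frozen backbone
#' (\code{spec$fine_tune = FALSE}) only the two task heads are
#' updated.
#'
#' @param train_frames List of annotated frames with images.
#' @param valid_frames Hold-out list; if \code{NULL}, an 80/20
#'   frame-level split of \code{train_frames} is made with the
#'   configuration seed.
#' @param spec A \code{\link{backbone_spec}}.
#' @param config A \code{\link{training_config}}.
#' @param n_keypoints,head_hidden,coord_activation Passed to
#'   \code{\link{build_model}}.
#' @param verbose Print one line per epoch.
#' @return Object of class \code{"mtk_fit"}: the best-epoch
#'   \code{model}, the per-epoch \code{history} data frame,
#'   \code{best_epoch}, \code{stopped_epoch}, the configuration, and
#'   the validation \code{metrics} report at the best epoch.
#' @seealso \code{\link{predict.mtk_fit}}, \code{\link{evaluate_model}}
#' @export
mtk_fit <- function(train_frames, valid_frames = NULL,
                    spec = backbone_spec("tiny_cnn"),
                    config = training_config(), n_keypoints = 11L,
                    head_hidden = 256L, coord_activation = "sigmoid",
                    verbose = FALSE) {
  if (length(train_frames) == 0L) stop("empty training set")
  if (is.null(valid_frames)) {
    sp <- split_dataset(train_frames, 0.8, seed = config$seed)
    train_frames <- sp$train
    valid_frames <- sp$valid
  }
  if (length(valid_frames) == 0L) stop("empty validation set")
  model <- build_model(spec, n_keypoints, head_hidden, coord_activation,
                       init_seed = config$seed)
  train_set <- .encode_set(train_frames, spec)
  valid_set <- .encode_set(valid_frames, spec)
  n <- length(train_frames)
  trainable <- trainable_param_names(model)
  opt <- opt_init(model$params, config$optimizer, config$learning_rate)
  w <- config$weights
  history <- NULL
  valid_totals <- numeric(0)
  best_total <- Inf
  best_params <- model$params
  best_epoch <- 0L
  stopped_epoch <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      t0 <- proc.time()[["elapsed"]]
      perm <- sample.int(n)
      tr1 <- 0; tr2_num <- 0; tr2_den <- 0
      i <- 1L
      while (i <= n) {
        j <- min(i + config$batch_size - 1L, n)
        idx <- perm[i:j]
        fw <- forward_model(model,
                            train_set$X[, , , idx, drop = FALSE],
                            keep_cache = TRUE)
        pres <- train_set$presence[idx, , drop = FALSE]
        ctru <- train_set$coords[idx, , drop = FALSE]
        mk <- train_set$mask[idx, , drop = FALSE]
        l1 <- classification_loss(pres, fw$probs)
        l2 <- log_cosh_loss(ctru, fw$coords, mk)
        if (!is.finite(l1) || !is.finite(l2)) {
          stop(sprintf("non-finite loss at epoch %d (loss1=%g, loss2=%g)",
                       epoch, l1, l2))
        }
        gr <- composite_loss_grad(pres, mk, fw$probs, ctru, fw$coords, w)
        grads <- backward_model(model, fw, gr$dlogits, gr$dcoords)
        st <- opt_step(opt, model$params, grads, trainable)
        opt <- st$opt
        model$params <- st$params
        nb <- j - i + 1L
        tr1 <- tr1 + l1 * nb
        tr2_num <- tr2_num + l2 * sum(mk)
        tr2_den <- tr2_den + sum(mk)
        i <- j + 1L
      }
      train_loss1 <- tr1 / n
      train_loss2 <- if (tr2_den > 0) tr2_num / tr2_den else 0
      vl <- .set_loss(model, valid_set, w)
      secs <- proc.time()[["elapsed"]] - t0
      history <- rbind(history, data.frame(
        epoch = epoch, train_total = w$w1 * train_loss1 + w$w2 * train_loss2,
        train_loss1 = train_loss1, train_loss2 = train_loss2,
        valid_total = vl$total, valid_loss1 = vl$loss1,
        valid_loss2 = vl$loss2, seconds = secs))
      if (verbose) {
        message(sprintf("epoch %3d  train %.5f  valid %.5f  (%.1fs)",
                        epoch, history$train_total[epoch], vl$total, secs))
      }
      valid_totals <- c(valid_totals, vl$total)
      if (vl$total < best_total) {
        best_total <- vl$total
        best_params <- model$params
        best_epoch <- epoch
      }
      stopped_epoch <- epoch
      if (should_stop(valid_totals, config$es_min_delta, config$es_patience)) {
        break
      }
    }
  })
  model$params <- best_params
  preds <- .predict_encoded(model, valid_set)
  metrics <- metrics_report(valid_set$encodings, preds)
  structure(list(model = model, history = history, config = config,
                 spec = spec, best_epoch = best_epoch,
                 stopped_epoch = stopped_epoch, metrics = metrics,
                 n_train = n, n_valid = length(valid_frames)),
            class = "mtk_fit")
}

# Predict from an already-encoded set (no re-preprocessing).
.predict_encoded <- function(model, set, chunk = 64L) {
  n <- nrow(set$presence)
  probs <- matrix(NA_real_, n, model$n_keypoints)
  coords <- matrix(NA_real_, n, 2L * model$n_keypoints)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    fw <- forward_model(model, set$X[, , , i:j, drop = FALSE])
    probs[i:j, ] <- fw$probs
    coords[i:j, ] <- fw$coords
    i <- j + 1L
  }
  structure(list(probabilities = probs, coords = coords), class = "mtk_pred")
}

#' Evaluate a model on a set of annotated frames
#'
#' Runs inference over all frames and applies the metric suite;
#' deterministic for fixed parameters.
#'
#' @param object An \code{mtk_fit} or \code{mtk_model}.
#' @param frames Non-empty list of annotated frames.
#' @param threshold Presence threshold.
#' @return A \code{\link{metrics_report}}.
#' @export
evaluate_model <- function(object, frames, threshold = 0.5) {
  model <- if (inherits(object, "mtk_fit")) object$model else object
  stopifnot(inherits(model, "mtk_model"))
  if (length(frames) == 0L) stop("empty evaluation set")
  preds <- predict_frames(model, frames)
  metrics_report(lapply(frames, encode_targets), preds, threshold)
}

#' @export
print.mtk_fit <- function(x, ...) {
  cat(sprintf(paste0("Multi-task keypoint model (%s): %d train / %d valid ",
                     "frames,\n  stopped at epoch %d, best epoch %d ",
                     "(valid loss %.5f)\n"),
              x$spec$name, x$n_train, x$n_valid, x$stopped_epoch,
              x$best_epoch, x$history$valid_total[x$best_epoch]))
  cat("Validation metrics at the best epoch:\n")
  print(x$metrics)
  invisible(x)
}

#' @export
summary.mtk_fit <- function(object, ...) {
  print(object)
  cat("\nPer-class validation metrics:\n")
  print(object$metrics$per_class, row.names = FALSE)
  invisible(object)
}

#' Predict method for fitted keypoint models
#'
#' @param object An \code{mtk_fit}.
#' @param newdata List of annotated frames.
#' @param ... Passed to \code{\link{predict_frames}}.
#' @return An \code{mtk_pred}.
#' @export
predict.mtk_fit <- function(object, newdata, ...) {
  predict_frames(object$model, newdata, ...)
}

#' Masked coordinate residuals
#'
#' Predicted minus annotated coordinates; slots of absent keypoints
#' are \code{NA}.
#'
#' @param object An \code{mtk_fit}.
#' @param newdata List of annotated frames.
#' @param ... Unused.
#' @return N x 22 matrix of residuals.
#' @export
residuals.mtk_fit <- function(object, newdata, ...) {
  pred <- predict_frames(object$model, newdata)
  enc <- lapply(newdata, encode_targets)
  truth <- do.call(rbind, lapply(enc, `[[`, "coords"))
  mask <- do.call(rbind, lapply(enc, `[[`, "mask"))
  r <- pred$coords - truth
  r[mask < 0.5] <- NA_real_
  colnames(r) <- colnames(pred$coords)
  r
}

#' Plot the training history
#'
#' Train and validation composite loss against epoch.
#'
#' @param x An \code{mtk_fit}.
#' @param ... Passed to \code{matplot}.
#' @export
plot.mtk_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_total, h$valid_total),
                    type = "l", lty = c(1, 2), col = c("black", "red"),
                    xlab = "epoch", ylab = "composite loss", ...)
  graphics::abline(v = x$best_epoch, col = "grey", lty = 3)
  graphics::legend("topright", c("train", "valid"), lty = c(1, 2),
                   col = c("black", "red"), bty = "n")
  invisible(x)
}

#' Write a training history CSV
#'
#' @param fit An \code{mtk_fit} (or its history data frame).
#' @param path Output path.
#' @return Invisibly, the data frame written.
#' @export
write_history_csv <- function(fit, path) {
  h <- if (inherits(fit, "mtk_fit")) fit$history else fit
  utils::write.csv(h, path, row.names = FALSE)
  invisible(h)
}
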