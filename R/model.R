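#' Backbone specification
#'
#' Describes the shared feature extractor: its name, input tensor side
#' length, feature dimensionality and whether its parameters are
#' trainable (fine-tuning) or frozen so that only the task heads learn.
#' The named large backbones carry the canonical input sizes and
#' feature dimensions of their published architectures
#' (\code{mobilenet_v2} 224/1280, \code{resnet_v2} 224/2048,
#' \code{inception_v3} 299/2048, \code{inception_resnet_v2} 299/1536,
#' \code{efficientnet_b5} 456/2048); in this package they are built as
#' randomly initialised stand-in extractors of the same interface
#' (no pretrained weights are downloaded). \code{tiny_cnn} (64/128) is
#' the desk-scale default used throughout the tests.
#'
#' @param name Backbone name.
#' @param fine_tune Train the backbone parameters too? Defaults to
#'   \code{TRUE} for \code{tiny_cnn} (trained from scratch) and
#'   \code{FALSE} for the named backbones.
#' @param input_size,feature_dim Override the canonical values.
#' @return List with class \code{"backbone_spec"}.
#' @export
backbone_spec <- function(name = c("tiny_cnn", "mobilenet_v2", "resnet_v2",
                                   "inception_v3", "inception_resnet_v2",
                                   "efficientnet_b5"),
                          fine_tune = NULL, input_size = NULL,
                          feature_dim = NULL) {
  canon <- list(tiny_cnn = c(64L, 128L),
                mobilenet_v2 = c(224L, 1280L),
                resnet_v2 = c(224L, 2048L),
                inception_v3 = c(299L, 2048L),
                inception_resnet_v2 = c(299L, 1536L),
                efficientnet_b5 = c(456L, 2048L))
  if (length(name) == 1L && !name %in% names(canon)) {
    stop("unknown backbone name: ", name)
  }
  name <- match.arg(name)
  if (is.null(input_size)) input_size <- canon[[name]][1]
  if (is.null(feature_dim)) feature_dim <- canon[[name]][2]
  if (is.null(fine_tune)) fine_tune <- name == "tiny_cnn"
  stopifnot(input_size > 0, feature_dim > 0)
  structure(list(name = name, input_size = as.integer(input_size),
                 feature_dim = as.integer(feature_dim),
                 fine_tune = isTRUE(fine_tune)),
            class = "backbone_spec")
}

.head_names <- c("cls1.W", "cls1.b", "cls2.W", "cls2.b",
                 "reg1.W", "reg1.b", "reg2.W", "reg2.b")

#' Build the multi-task keypoint model
#'
#' Hard parameter sharing: one convolutional feature extractor feeds
#' two heads, a multi-label classifier emitting \code{n_keypoints}
#' presence probabilities (sigmoid) and a coordinate regressor emitting
#' \code{2 * n_keypoints} values. Each head is
#' feature -> hidden (ReLU) -> output. The backbone is four 3x3
#' stride-2 convolution blocks; for \code{tiny_cnn} the final feature
#' map is projected channel-wise and flattened (keeping spatial
#' information, which coordinate regression needs), for the named
#' backbones it is globally average-pooled and projected to the
#' canonical feature dimension.
#'
#' @param spec A \code{\link{backbone_spec}}.
#' @param n_keypoints Number of keypoint classes (default 11).
#' @param head_hidden Hidden width of each head (default 256).
#' @param coord_activation \code{"sigmoid"} (coordinates natively in
#'   [0, 1]) or \code{"linear"}.
#' @param init_seed Seed for parameter initialization.
#' @return List with class \code{"mtk_model"}.
#' @export
build_model <- function(spec, n_keypoints = 11L, head_hidden = 256L,
                        coord_activation = c("sigmoid", "linear"),
                        init_seed = 1L) {
  stopifnot(inherits(spec, "backbone_spec"))
  coord_activation <- match.arg(coord_activation)
  if (n_keypoints < 1L) stop("n_keypoints must be >= 1")
  channels <- c(8L, 16L, 32L, 64L)
  geoms <- list()
  H <- spec$input_size
  Cin <- 3L
  for (i in 1:4) {
    geoms[[i]] <- conv_geom(H, H, Cin, channels[i])
    H <- geoms[[i]]$OH
    Cin <- channels[i]
  }
  g2 <- H * H
  feature_mode <- if (spec$name == "tiny_cnn" && spec$feature_dim %% g2 == 0L) {
    "flatten"
  } else "gap"
  c_feat <- if (feature_mode == "flatten") spec$feature_dim %/% g2 else spec$feature_dim
  d <- spec$feature_dim
  h <- as.integer(head_hidden)
  params <- with_seed(init_seed, {
    p <- list()
    for (i in 1:4) {
      gm <- geoms[[i]]
      p[[paste0("conv", i, ".W")]] <-
        matrix(stats::rnorm(gm$KKC * gm$Cout, 0, sqrt(2 / gm$KKC)),
               gm$KKC, gm$Cout)
      p[[paste0("conv", i, ".b")]] <- numeric(gm$Cout)
    }
    p[["feat.W"]] <- matrix(stats::rnorm(channels[4] * c_feat, 0,
                                         sqrt(2 / channels[4])),
                            channels[4], c_feat)
    p[["feat.b"]] <- numeric(c_feat)
    p[["cls1.W"]] <- matrix(stats::rnorm(d * h, 0, sqrt(2 / d)), d, h)
    p[["cls1.b"]] <- numeric(h)
    p[["cls2.W"]] <- matrix(stats::rnorm(h * n_keypoints, 0, sqrt(1 / h)),
                            h, n_keypoints)
    p[["cls2.b"]] <- numeric(n_keypoints)
    p[["reg1.W"]] <- matrix(stats::rnorm(d * h, 0, sqrt(2 / d)), d, h)
    p[["reg1.b"]] <- numeric(h)
    p[["reg2.W"]] <- matrix(stats::rnorm(h * 2 * n_keypoints, 0, sqrt(1 / h)),
                            h, 2L * n_keypoints)
    p[["reg2.b"]] <- numeric(2L * n_keypoints)
    p
  })
  backbone_names <- setdiff(names(params), .head_names)
  structure(list(spec = spec, n_keypoints = as.integer(n_keypoints),
                 head_hidden = h, coord_activation = coord_activation,
                 channels = channels, geoms = geoms, g = H, g2 = g2,
                 c_feat = c_feat, feature_mode = feature_mode,
                 params = params, backbone_names = backbone_names),
            class = "mtk_model")
}

#' Trainable and frozen parameter counts
#'
#' @param model An \code{mtk_model}.
#' @return Named integer vector \code{c(trainable, non_trainable)};
#'   with \code{fine_tune = FALSE} all backbone parameters are
#'   non-trainable.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "mtk_model"))
  sizes <- vapply(model$params, length, integer(1))
  head_n <- sum(sizes[.head_names])
  back_n <- sum(sizes[model$backbone_names])
  if (model$spec$fine_tune) {
    c(trainable = head_n + back_n, non_trainable = 0L)
  } else {
    c(trainable = head_n, non_trainable = back_n)
  }
}

trainable_param_names <- function(model) {
  if (model$spec$fine_tune) names(model$params) else .head_names
}

#' Preprocess a frame for the model
#'
#' Bilinear resize of the grayscale image to the backbone's input size,
#' replication to three channels, and scaling to [0, 1].
#'
#' @param frame An \code{aort_frame} (or a plain 0-255 matrix).
#' @param spec A \code{\link{backbone_spec}}.
#' @return Numeric array \code{input_size x input_size x 3}.
#' @export
preprocess <- function(frame, spec) {
  img <- if (inherits(frame, "aort_frame")) frame$image else frame
  if (is.null(img) || length(img) == 0L) stop("frame has no image")
  S <- spec$input_size
  if (!all(dim(img) == c(S, S))) {
    img <- EBImage::resize(img, w = S, h = S)
  }
  x <- img / 255
  array(rep(as.vector(x), 3L), c(S, S, 3L))
}

# Stack frames into one input batch array (S, S, 3, N).
preprocess_batch <- function(frames, spec) {
  S <- spec$input_size
  X <- array(0, c(S, S, 3L, length(frames)))
  for (i in seq_along(frames)) X[, , , i] <- preprocess(frames[[i]], spec)
  X
}

# Full forward pass. Returns probabilities, coordinates and (when
# `keep_cache`) everything the backward pass needs.
forward_model <- function(model, X, keep_cache = FALSE) {
  p <- model$params
  N <- dim(X)[4]
  A <- X
  conv_caches <- vector("list", 4L)
  for (i in 1:4) {
    cf <- conv_forward(A, model$geoms[[i]], p[[paste0("conv", i, ".W")]],
                       p[[paste0("conv", i, ".b")]])
    conv_caches[[i]] <- if (keep_cache) cf[c("P", "pos", "N")] else NULL
    A <- cf$out
  }
  g2 <- model$g2
  C4 <- model$channels[4]
  if (model$feature_mode == "flatten") {
    Pp <- matrix(aperm(array(A, c(g2, C4, N)), c(1, 3, 2)), g2 * N, C4)
    fc <- dense_forward(Pp, p[["feat.W"]], p[["feat.b"]], relu = TRUE)
    Fmat <- t(matrix(aperm(array(fc$out, c(g2, N, model$c_feat)), c(1, 3, 2)),
                     g2 * model$c_feat, N))
  } else {
    gap <- t(matrix(colMeans(matrix(aperm(array(A, c(g2, C4, N)), c(1, 3, 2)),
                                    g2, C4 * N)), C4, N))
    fc <- dense_forward(gap, p[["feat.W"]], p[["feat.b"]], relu = TRUE)
    Fmat <- fc$out
  }
  h1c <- dense_forward(Fmat, p[["cls1.W"]], p[["cls1.b"]], relu = TRUE)
  zc <- dense_forward(h1c$out, p[["cls2.W"]], p[["cls2.b"]])
  probs <- sigmoid(zc$out)
  h1r <- dense_forward(Fmat, p[["reg1.W"]], p[["reg1.b"]], relu = TRUE)
  zr <- dense_forward(h1r$out, p[["reg2.W"]], p[["reg2.b"]])
  coords <- if (model$coord_activation == "sigmoid") sigmoid(zr$out) else zr$out
  out <- list(probs = probs, coords = coords, N = N)
  if (keep_cache) {
    out$conv <- conv_caches
    out$fc <- fc
    out$h1c <- h1c; out$zc <- zc
    out$h1r <- h1r; out$zr <- zr
  }
  out
}

# Backward pass from gradients w.r.t. classifier logits and regressor
# output; returns the flat named gradient list.
backward_model <- function(model, fwd, dlogits, dcoords) {
  p <- model$params
  N <- fwd$N
  du <- if (model$coord_activation == "sigmoid") {
    dcoords * fwd$coords * (1 - fwd$coords)
  } else dcoords
  grads <- list()
  bc2 <- dense_backward(dlogits, fwd$zc, p[["cls2.W"]])
  grads[["cls2.W"]] <- bc2$dW; grads[["cls2.b"]] <- bc2$db
  bc1 <- dense_backward(bc2$dX, fwd$h1c, p[["cls1.W"]])
  grads[["cls1.W"]] <- bc1$dW; grads[["cls1.b"]] <- bc1$db
  br2 <- dense_backward(du, fwd$zr, p[["reg2.W"]])
  grads[["reg2.W"]] <- br2$dW; grads[["reg2.b"]] <- br2$db
  br1 <- dense_backward(br2$dX, fwd$h1r, p[["reg1.W"]])
  grads[["reg1.W"]] <- br1$dW; grads[["reg1.b"]] <- br1$db
  dF <- bc1$dX + br1$dX
  g2 <- model$g2
  C4 <- model$channels[4]
  if (model$feature_mode == "flatten") {
    dOut <- matrix(aperm(array(t(dF), c(g2, model$c_feat, N)), c(1, 3, 2)),
                   g2 * N, model$c_feat)
    bf <- dense_backward(dOut, fwd$fc, p[["feat.W"]])
    grads[["feat.W"]] <- bf$dW; grads[["feat.b"]] <- bf$db
    dA <- array(aperm(array(bf$dX, c(g2, N, C4)), c(1, 3, 2)),
                c(model$g, model$g, C4, N))
  } else {
    bf <- dense_backward(dF, fwd$fc, p[["feat.W"]])
    grads[["feat.W"]] <- bf$dW; grads[["feat.b"]] <- bf$db
    dA <- array(rep(as.vector(t(bf$dX) / g2), each = g2),
                c(model$g, model$g, C4, N))
  }
  if (model$spec$fine_tune) {
    for (i in 4:1) {
      cb <- conv_backward(dA, fwd$conv[[i]], model$geoms[[i]],
                          p[[paste0("conv", i, ".W")]])
      grads[[paste0("conv", i, ".W")]] <- cb$dW
      grads[[paste0("conv", i, ".b")]] <- cb$db
      dA <- cb$dA
    }
  }
  grads
}

#' Predict keypoint probabilities and coordinates
#'
#' Deterministic inference over a list of frames.
#'
#' @param model An \code{mtk_model}.
#' @param frames List of \code{aort_frame}s (with images).
#' @param batch_size Frames per forward pass.
#' @return List with class \code{"mtk_pred"}: \code{probabilities}
#'   (N x n_keypoints matrix) and \code{coords} (N x 2 n_keypoints),
#'   rows in input order.
#' @export
predict_frames <- function(model, frames, batch_size = 32L) {
  stopifnot(inherits(model, "mtk_model"), length(frames) > 0L)
  n <- length(frames)
  probs <- matrix(NA_real_, n, model$n_keypoints)
  coords <- matrix(NA_real_, n, 2L * model$n_keypoints)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    X <- preprocess_batch(frames[i:j], model$spec)
    fw <- forward_model(model, X)
    probs[i:j, ] <- fw$probs
    coords[i:j, ] <- fw$coords
    i <- j + 1L
  }
  if (model$n_keypoints == 11L) {
    colnames(probs) <- kp_labels()
    colnames(coords) <- paste0(rep(kp_labels(), each = 2), c("_x", "_y"))
  }
  structure(list(probabilities = probs, coords = coords),
            class = "mtk_pred")
}

# Single-frame prediction bundle.
prediction_bundle <- function(pred, i) {
  list(probabilities = pred$probabilities[i, ], coords = pred$coords[i, ])
}

#' Save / load a model checkpoint
#'
#' Single-file serialized parameters plus the backbone specification
#' and a schema version; the round trip is exact.
#'
#' @param model An \code{mtk_model}.
#' @param path Checkpoint file path.
#' @return \code{load_checkpoint} returns the restored
#'   \code{mtk_model}.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(version = 1L, spec = model$spec,
               n_keypoints = model$n_keypoints,
               head_hidden = model$head_hidden,
               coord_activation = model$coord_activation,
               params = model$params),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$version) || ck$version != 1L) {
    stop("unsupported checkpoint schema version")
  }
  model <- build_model(ck$spec, ck$n_keypoints, ck$head_hidden,
                       ck$coord_activation)
  model$params <- ck$params
  model
}

#' @export
print.mtk_model <- function(x, ...) {
  cp <- count_parameters(x)
  cat(sprintf(paste0("<mtk_model backbone=%s (input %d, features %d, ",
                     "fine_tune=%s), %d keypoints, %s trainable / %s frozen ",
                     "parameters>\n"),
              x$spec$name, x$spec$input_size, x$spec$feature_dim,
              x$spec$fine_tune, x$n_keypoints,
              format(cp[["trainable"]], big.mark = ","),
              format(cp[["non_trainable"]], big.mark = ",")))
  invisible(x)
}
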