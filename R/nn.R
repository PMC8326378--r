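# Low-level neural-network machinery: strided 3x3 convolutions via a
# precomputed sparse im2col operator (Matrix), ReLU, dense layers, and
# Adam / Rectified Adam updates. Activations are 4-d arrays
# (height, width, channels, batch); dense activations are
# (batch x features) matrices. Everything is plain double arithmetic,
# so runs are bit-reproducible for a fixed seed.

# Geometry + sparse patch-extraction operator for one conv layer.
conv_geom <- function(H, W, Cin, Cout, k = 3L, stride = 2L, pad = 1L) {
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  OH <- (Hp - k) %/% stride + 1L
  OW <- (Wp - k) %/% stride + 1L
  M <- OH * OW
  KKC <- k * k * Cin
  oh_v <- rep(seq_len(OH), times = OW)
  ow_v <- rep(seq_len(OW), each = OH)
  kh_v <- rep(seq_len(k), times = k * Cin)
  kw_v <- rep(rep(seq_len(k), each = k), times = Cin)
  c_v <- rep(seq_len(Cin), each = k * k)
  R <- outer((oh_v - 1L) * stride, kh_v, "+")
  CC <- outer((ow_v - 1L) * stride, kw_v, "+")
  SRC <- R + (CC - 1L) * Hp +
    matrix((c_v - 1L) * (Hp * Wp), M, KKC, byrow = TRUE)
  S <- Matrix::sparseMatrix(i = seq_len(M * KKC), j = as.vector(SRC), x = 1,
                            dims = c(M * KKC, Hp * Wp * Cin))
  list(H = H, W = W, Cin = Cin, Cout = Cout, k = k, stride = stride,
       pad = pad, Hp = Hp, Wp = Wp, OH = OH, OW = OW, M = M, KKC = KKC,
       S = S)
}

conv_forward <- function(A, geom, Wt, b) {
  N <- dim(A)[4]
  Apad <- array(0, c(geom$Hp, geom$Wp, geom$Cin, N))
  Apad[geom$pad + seq_len(geom$H), geom$pad + seq_len(geom$W), , ] <- A
  Amat <- matrix(Apad, nrow = geom$Hp * geom$Wp * geom$Cin)
  PS <- as.matrix(geom$S %*% Amat)
  P <- matrix(aperm(array(PS, c(geom$M, geom$KKC, N)), c(1, 3, 2)),
              geom$M * N, geom$KKC)
  Z <- sweep(P %*% Wt, 2L, b, "+")
  Apos <- Z > 0
  Aout <- array(aperm(array(Z * Apos, c(geom$M, N, geom$Cout)), c(1, 3, 2)),
                c(geom$OH, geom$OW, geom$Cout, N))
  list(out = Aout, P = P, pos = Apos, N = N)
}

conv_backward <- function(dAout, cache, geom, Wt) {
  N <- cache$N
  dZ <- matrix(aperm(array(dAout, c(geom$M, geom$Cout, N)), c(1, 3, 2)),
               geom$M * N, geom$Cout)
  dZ <- dZ * cache$pos
  dW <- crossprod(cache$P, dZ)
  db <- colSums(dZ)
  dP <- tcrossprod(dZ, Wt)
  dPS <- matrix(aperm(array(dP, c(geom$M, N, geom$KKC)), c(1, 3, 2)),
                geom$M * geom$KKC, N)
  dAmat <- as.matrix(Matrix::crossprod(geom$S, dPS))
  dApad <- array(dAmat, c(geom$Hp, geom$Wp, geom$Cin, N))
  dA <- dApad[geom$pad + seq_len(geom$H), geom$pad + seq_len(geom$W), , ,
              drop = FALSE]
  list(dA = dA, dW = dW, db = db)
}

dense_forward <- function(X, Wt, b, relu = FALSE) {
  Z <- sweep(X %*% Wt, 2L, b, "+")
  if (relu) {
    pos <- Z > 0
    list(out = Z * pos, X = X, pos = pos)
  } else {
    list(out = Z, X = X, pos = NULL)
  }
}

dense_backward <- function(dOut, cache, Wt) {
  if (!is.null(cache$pos)) dOut <- dOut * cache$pos
  list(dX = tcrossprod(dOut, Wt),
       dW = crossprod(cache$X, dOut),
       db = colSums(dOut))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# ---- optimizers -----------------------------------------------------

opt_init <- function(params, optimizer = c("rectified_adam", "adam"),
                     lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  optimizer <- match.arg(optimizer)
  zeros <- lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p)))
  list(type = optimizer, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       t = 0L, m = zeros, v = zeros)
}

# One update over the named flat parameter list; only `trainable`
# entries are touched. Rectified Adam follows Liu et al.'s variance
# rectification: plain momentum SGD while the adaptive variance is
# untrustworthy, rectified Adam afterwards.
opt_step <- function(opt, params, grads, trainable) {
  opt$t <- opt$t + 1L
  t <- opt$t
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^t; bc2 <- 1 - b2^t
  use_rect <- opt$type == "rectified_adam"
  if (use_rect) {
    rho_inf <- 2 / (1 - b2) - 1
    rho_t <- rho_inf - 2 * t * b2^t / bc2
  }
  for (nm in trainable) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    m_hat <- opt$m[[nm]] / bc1
    if (!use_rect || rho_t > 4) {
      v_hat <- sqrt(opt$v[[nm]] / bc2) + opt$eps
      r <- 1
      if (use_rect) {
        r <- sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                    ((rho_inf - 4) * (rho_inf - 2) * rho_t))
      }
      params[[nm]] <- params[[nm]] - opt$lr * r * m_hat / v_hat
    } else {
      params[[nm]] <- params[[nm]] - opt$lr * m_hat
    }
  }
  list(opt = opt, params = params)
}
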