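## Lightweight 3D segmentation building blocks: depthwise separable
## convolution, parameter accounting, residual self-similarity mixing,
## decoder softmax, skip addition and a hybrid CE+Dice loss — plus a toy
## encoder-decoder assembled from them, trainable with hand-derived
## analytic gradients (verified against finite differences in the tests).

## Shift a 3D array: out(x) = arr(x + u), zero outside the domain.
shift3 <- function(arr, u) {
  d <- dim(arr)
  out <- array(0, dim = d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- u[ax]
    dst[[ax]] <- seq_len(d[ax]) [seq_len(d[ax]) + s >= 1 & seq_len(d[ax]) + s <= d[ax]]
    src[[ax]] <- dst[[ax]] + s
    if (length(dst[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Depthwise convolution
#'
#' Processes each channel independently:
#' `Y_c(i,j,k) = sum_{u,v,w} X_c(i+u, j+v, k+w) * K_c(u,v,w)` (correlation
#' convention), with zero padding so spatial dimensions are preserved.
#'
#' @param X 4D feature array `[H, W, D, C]`.
#' @param K per-channel kernels, a 4D array `[k, k, k, C]` with odd `k`.
#' @return A 4D array the size of `X`.
#' @export
dwconv <- function(X, K) {
  dX <- dim(X); dK <- dim(K)
  if (length(dX) != 4L || length(dK) != 4L) stop("dwconv: X and K must be 4D arrays")
  if (dX[4] != dK[4]) stop("dwconv: channel mismatch (", dX[4], " vs ", dK[4], ")")
  if (any(dK[1:3] %% 2 == 0)) stop("dwconv: kernel spatial size must be odd")
  r <- (dK[1:3] - 1) / 2
  out <- array(0, dim = dX)
  for (c in seq_len(dX[4])) {
    Xc <- X[, , , c]
    acc <- array(0, dim = dX[1:3])
    for (u in -r[1]:r[1]) for (v in -r[2]:r[2]) for (w in -r[3]:r[3]) {
      kv <- K[u + r[1] + 1, v + r[2] + 1, w + r[3] + 1, c]
      if (kv != 0) acc <- acc + kv * shift3(Xc, c(u, v, w))
    }
    out[, , , c] <- acc
  }
  out
}

## Gradients of dwconv under zero padding.
dwconv_backward <- function(X, K, dY) {
  dX_dim <- dim(X); dK_dim <- dim(K)
  r <- (dK_dim[1:3] - 1) / 2
  dX <- array(0, dim = dX_dim)
  dK <- array(0, dim = dK_dim)
  for (c in seq_len(dX_dim[4])) {
    Xc <- X[, , , c]; dYc <- dY[, , , c]
    accX <- array(0, dim = dX_dim[1:3])
    for (u in -r[1]:r[1]) for (v in -r[2]:r[2]) for (w in -r[3]:r[3]) {
      kv <- K[u + r[1] + 1, v + r[2] + 1, w + r[3] + 1, c]
      accX <- accX + kv * shift3(dYc, -c(u, v, w))
      dK[u + r[1] + 1, v + r[2] + 1, w + r[3] + 1, c] <- sum(dYc * shift3(Xc, c(u, v, w)))
    }
    dX[, , , c] <- accX
  }
  list(dX = dX, dK = dK)
}

#' Parameter counts of depthwise-separable vs standard convolution
#'
#' Depthwise-separable: `c_in * k^2 + c_in * c_out` (depthwise kernels plus
#' the pointwise projection); standard: `c_in * c_out * k^2`. The printed
#' formulas use `k^2`; set `cubic = TRUE` for the `k^3` variant matching a
#' fully 3D kernel.
#'
#' @param c_in,c_out,k positive integers.
#' @param cubic use `k^3` instead of `k^2`.
#' @return Named numeric `c(p_sep, p_std)`.
#' @export
param_count <- function(c_in, c_out, k, cubic = FALSE) {
  stopifnot(c_in >= 1, c_out >= 1, k >= 1)
  kk <- if (cubic) k^3 else k^2
  c(p_sep = c_in * kk + c_in * c_out, p_std = c_in * c_out * kk)
}

## Row-wise softmax with max subtraction.
row_softmax <- function(Z) {
  mx <- apply(Z, 1, max)
  E <- exp(Z - mx)
  E / rowSums(E)
}

## Layer normalization over the feature dimension (rows are positions).
layer_norm <- function(F2, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(F2)
  xc <- F2 - mu
  v <- rowMeans(xc^2)
  sd <- sqrt(v + eps)
  xhat <- xc / sd
  list(out = sweep(xhat, 2, gamma, "*") + matrix(beta, nrow(F2), length(beta), byrow = TRUE),
       xhat = xhat, sd = sd)
}

layer_norm_backward <- function(cache, gamma, dOut) {
  dgamma <- colSums(dOut * cache$xhat)
  dbeta <- colSums(dOut)
  dxhat <- sweep(dOut, 2, gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- (dxhat - m1 - cache$xhat * m2) / cache$sd
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

#' Residual self-similarity mixing block
#'
#' Given features `F` (positions in rows, `d` columns):
#' `F' = Norm(F) + F W1 + b1`; a row-stochastic self-similarity matrix
#' `S = softmax(F_i . F_j / sqrt(d))`; and `F_out = F' + S F'` — residual
#' attention-weighted mixing of the projected features. `Norm` is layer
#' normalization over the feature dimension (or the identity).
#'
#' @param F numeric matrix, positions x d.
#' @param params list with `W1` (d x d), `b1` (length d), and for layer
#'   norm `gamma`, `beta` (length d); `norm` is `"layer"` or `"identity"`.
#' @return List with `out` (positions x d), `S`, and `Fp` (the projected
#'   features `F'`).
#' @export
rvm_block <- function(F, params) {
  d <- ncol(F)
  if (!is.matrix(params$W1) || any(dim(params$W1) != d)) stop("rvm_block: W1 must be d x d")
  if (length(params$b1) != d) stop("rvm_block: b1 must have length d")
  norm <- params$norm %||% "layer"
  Fn <- if (norm == "identity") F else {
    layer_norm(F, params$gamma, params$beta)$out
  }
  Fp <- Fn + F %*% params$W1 + matrix(params$b1, nrow(F), d, byrow = TRUE)
  S <- row_softmax(F %*% t(F) / sqrt(d))
  list(out = Fp + S %*% Fp, S = S, Fp = Fp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Voxel-wise class probabilities by channel softmax
#'
#' `P(i,j,k,c) = exp(F(i,j,k,c)) / sum_c' exp(F(i,j,k,c'))`; every voxel's
#' class probabilities sum to 1.
#'
#' @param F_dec 4D logits array `[H, W, D, K]` with `K >= 2` class channels.
#' @return A 4D probability array of the same shape.
#' @export
decoder_softmax <- function(F_dec) {
  d <- dim(F_dec)
  if (length(d) != 4L || d[4] < 2L) stop("decoder_softmax: need a 4D array with K >= 2 class channels")
  P <- row_softmax(matrix(F_dec, ncol = d[4]))
  array(P, dim = d)
}

#' Skip connection: upsample and add encoder features
#'
#' `F_up = Interpolate(F_low) + F_skip`, with trilinear (separable linear)
#' upsampling of the low-resolution features to the skip tensor's spatial
#' dimensions.
#'
#' @param F_low 4D array `[h, w, d, C]`.
#' @param F_skip 4D array `[H, W, D, C]` with the same channel count.
#' @return 4D array the size of `F_skip`.
#' @export
skip_add <- function(F_low, F_skip) {
  dl <- dim(F_low); ds <- dim(F_skip)
  if (length(dl) != 4L || length(ds) != 4L || dl[4] != ds[4]) {
    stop("skip_add: both inputs must be 4D with matching channels")
  }
  out <- array(0, dim = ds)
  for (c in seq_len(ds[4])) out[, , , c] <- resize3(F_low[, , , c], ds[1:3])
  out + F_skip
}

#' Hybrid cross-entropy plus Dice loss
#'
#' `L = L_CE + eps * L_Dice`: mean voxel-wise negative log-probability of
#' the true class (log clamped at `clamp`), plus one minus the mean soft
#' Dice over classes (`2 sum(P Y) / (sum P + sum Y)`; a class absent from
#' both prediction and truth counts as perfect). `eps` balances voxel-level
#' accuracy against shape consistency.
#'
#' @param P probability matrix (voxels x K) or 4D array `[.,.,.,K]`; rows
#'   must sum to 1 within 1e-6.
#' @param Y one-hot truth of the same shape.
#' @param eps Dice weight (default 1).
#' @param clamp lower clamp inside the log.
#' @return Scalar loss, with attributes `ce` and `dice_loss`.
#' @export
hybrid_loss <- function(P, Y, eps = 1, clamp = 1e-7) {
  if (length(dim(P)) == 4L) P <- matrix(P, ncol = dim(P)[4])
  if (length(dim(Y)) == 4L) Y <- matrix(Y, ncol = dim(Y)[4])
  if (any(abs(rowSums(P) - 1) > 1e-6)) stop("hybrid_loss: probability rows must sum to 1")
  N <- nrow(P); K <- ncol(P)
  ce <- -mean(log(pmax(rowSums(P * Y), clamp)))
  A <- colSums(P * Y)
  B <- colSums(P) + colSums(Y)
  d_c <- ifelse(B > 0, 2 * A / B, 1)
  dl <- 1 - mean(d_c)
  out <- ce + eps * dl
  attr(out, "ce") <- ce
  attr(out, "dice_loss") <- dl
  out
}

## d loss / d logits for softmax probabilities P = softmax(logits).
hybrid_loss_grad_logits <- function(P, Y, eps = 1, clamp = 1e-7) {
  N <- nrow(P); K <- ncol(P)
  g <- -(1 / N) * Y / pmax(P, clamp)          # dCE/dP
  A <- colSums(P * Y)
  B <- colSums(P) + colSums(Y)
  gd <- matrix(0, N, K)
  nz <- B > 0
  gd[, nz] <- sweep(sweep(Y[, nz, drop = FALSE], 2, 2 * B[nz], "*"), 2, 2 * A[nz], "-")
  gd[, nz] <- sweep(gd[, nz, drop = FALSE], 2, B[nz]^2, "/")
  g <- g + eps * (-(1 / K) * gd)               # dDice-loss/dP
  P * (g - rowSums(g * P))                     # softmax Jacobian
}

## ---- toy encoder-decoder assembled from the blocks ---------------------

avgpool2 <- function(X4) {
  d <- dim(X4)
  out <- array(0, dim = c(d[1:3] %/% 2L, d[4]))
  for (c in seq_len(d[4])) out[, , , c] <- downsample3(X4[, , , c], 2L)
  out
}

avgpool2_backward <- function(dY4, in_shape) {
  d <- dim(dY4)
  out <- array(0, dim = c(in_shape, d[4]))
  ix <- rep(seq_len(d[1]), each = 2L)[seq_len(in_shape[1])]
  iy <- rep(seq_len(d[2]), each = 2L)[seq_len(in_shape[2])]
  iz <- rep(seq_len(d[3]), each = 2L)[seq_len(in_shape[3])]
  for (c in seq_len(d[4])) out[, , , c] <- dY4[ix, iy, iz, c] / 8
  out
}

resize4 <- function(X4, out_shape, adjoint = FALSE) {
  d <- dim(X4)
  out <- array(0, dim = c(out_shape, d[4]))
  Ms <- lapply(1:3, function(ax) {
    M <- resize_matrix(if (adjoint) out_shape[ax] else d[ax],
                       if (adjoint) d[ax] else out_shape[ax])
    if (adjoint) t(M) else M
  })
  for (c in seq_len(d[4])) {
    v <- X4[, , , c]
    for (ax in 1:3) if (dim(v)[ax] != out_shape[ax]) v <- ttm3(v, Ms[[ax]], ax)
    out[, , , c] <- v
  }
  out
}

#' Initialize the toy segmentation network
#'
#' A two-level encoder-decoder built from the exported blocks: channel
#' embedding, depthwise convolution + ReLU at full resolution, average-pool
#' downsampling, a residual self-similarity mixing block at the coarse
#' level, trilinear upsampling with a skip addition, a decoder depthwise
#' convolution + ReLU, and a pointwise classification head with channel
#' softmax.
#'
#' @param channels feature width (8-16 is the intended toy range).
#' @param classes number of output classes K.
#' @param k depthwise kernel size (odd).
#' @param seed integer seed for the initialization.
#' @return A named list of parameter arrays of class `toy_net`.
#' @export
init_toy_net <- function(channels = 8L, classes = 3L, k = 3L, seed = 1L) {
  set.seed(seed)
  C <- channels
  rn <- function(...) array(stats::rnorm(prod(c(...)), sd = 0.3), dim = c(...))
  structure(list(
    We = rn(1, C), be = numeric(C),
    K1 = rn(k, k, k, C) / k, gamma = rep(1, C), beta = numeric(C),
    W1 = rn(C, C) / sqrt(C), b1 = numeric(C),
    K2 = rn(k, k, k, C) / k, b2 = numeric(C),
    Wh = rn(C, classes), bh = numeric(classes)
  ), class = "toy_net")
}

#' Total parameter count of a toy network
#'
#' @param net a `toy_net`.
#' @return Integer: the number of scalar parameters, by exhaustive
#'   enumeration of the parameter arrays.
#' @export
toy_net_params <- function(net) sum(vapply(unclass(net), length, integer(1)))

toy_forward <- function(net, x, Y, eps = 1, with_cache = FALSE) {
  n <- dim(x); C <- ncol(net$We); K <- ncol(net$Wh)
  N <- prod(n)
  X1 <- matrix(as.vector(x), ncol = 1)
  F1 <- X1 %*% net$We + matrix(net$be, N, C, byrow = TRUE)
  F1a <- array(F1, dim = c(n, C))
  D1 <- dwconv(F1a, net$K1)
  R1 <- pmax(D1, 0)
  P2 <- avgpool2(R1)
  m <- dim(P2)[1:3]
  F2 <- matrix(P2, ncol = C)
  ln <- layer_norm(F2, net$gamma, net$beta)
  Fp <- ln$out + F2 %*% net$W1 + matrix(net$b1, nrow(F2), C, byrow = TRUE)
  S <- row_softmax(F2 %*% t(F2) / sqrt(C))
  Mo <- Fp + S %*% Fp
  U <- skip_add(array(Mo, dim = c(m, C)), R1)
  D2 <- dwconv(U, net$K2)
  R2 <- pmax(sweep_add4(D2, net$b2), 0)
  Um <- matrix(R2, ncol = C)
  logits <- Um %*% net$Wh + matrix(net$bh, N, K, byrow = TRUE)
  P <- row_softmax(logits)
  loss <- hybrid_loss(P, Y, eps = eps)
  res <- list(loss = as.numeric(loss), P = P,
              ce = attr(loss, "ce"), dice_loss = attr(loss, "dice_loss"))
  if (with_cache) {
    res$cache <- list(X1 = X1, F1a = F1a, D1 = D1, R1 = R1, F2 = F2, ln = ln,
                      Fp = Fp, S = S, Mo = Mo, U = U, D2 = D2, R2 = R2,
                      Um = Um, n = n, m = m)
  }
  res
}

toy_backward <- function(net, cache, P, Y, eps = 1) {
  C <- ncol(net$We); K <- ncol(net$Wh)
  n <- cache$n; m <- cache$m; N <- prod(n)
  dlogits <- hybrid_loss_grad_logits(P, Y, eps = eps)
  dWh <- t(cache$Um) %*% dlogits
  dbh <- colSums(dlogits)
  dR2 <- array(dlogits %*% t(net$Wh), dim = c(n, C))
  dD2 <- dR2 * (sweep_add4(cache$D2, net$b2) > 0)
  db2 <- apply(dD2, 4, sum)
  dw2 <- dwconv_backward(cache$U, net$K2, dD2)
  dU <- matrix(dw2$dX, ncol = C)
  dR1 <- array(dU, dim = c(n, C))                       # skip branch
  dMo4 <- resize4(array(dU, dim = c(n, C)), m, adjoint = TRUE)
  dMo <- matrix(dMo4, ncol = C)
  ## RVM backward
  dFp <- dMo + t(cache$S) %*% dMo
  dS <- dMo %*% t(cache$Fp)
  dZ <- cache$S * (dS - rowSums(dS * cache$S))
  dF2 <- (dZ + t(dZ)) %*% cache$F2 / sqrt(C)
  dF2 <- dF2 + dFp %*% t(net$W1)
  dW1 <- t(cache$F2) %*% dFp
  db1 <- colSums(dFp)
  lnb <- layer_norm_backward(cache$ln, net$gamma, dFp)
  dF2 <- dF2 + lnb$dX
  dP2 <- array(dF2, dim = c(m, C))
  dR1 <- dR1 + avgpool2_backward(dP2, n)
  dD1 <- dR1 * (cache$D1 > 0)
  dw <- dwconv_backward(cache$F1a, net$K1, dD1)
  dF1 <- matrix(dw$dX, ncol = C)
  dWe <- t(cache$X1) %*% dF1
  dbe <- colSums(dF1)
  list(We = dWe, be = dbe, K1 = dw$dK, gamma = lnb$dgamma, beta = lnb$dbeta,
       W1 = dW1, b1 = db1, K2 = dw2$dK, b2 = db2, Wh = dWh, bh = dbh)
}

## add a per-channel bias to a [H,W,D,C] tensor
sweep_add4 <- function(X, b) {
  d <- dim(X)
  X + array(rep(b, each = prod(d[1:3])), dim = d)
}

#' Overfit the toy network on a single labeled volume
#'
#' Heavy-ball gradient descent on the hybrid loss, all gradients analytic,
#' with a nonmonotone bold-driver step control: a step is accepted while
#' the loss stays within 5% of the best value seen (heavy-ball iterations
#' are transiently nonmonotone even when converging); a worse step is
#' rolled back, the momentum reset and the learning rate halved, and
#' accepted steps grow the rate slightly. The best iterate is tracked and
#' returned, so the reported loss trace (`loss`, the running best) is
#' non-increasing; the raw per-step values are in `loss_raw`. A desk-scale
#' optimization sanity check for the blocks: the loss on a single phantom
#' should collapse well below its initial value.
#'
#' @param image 3D intensity array (e.g. a 16^3 phantom).
#' @param labels 3D integer array of class indices (0-based or any coding;
#'   re-coded internally to 1..K).
#' @param steps gradient steps (default 500).
#' @param lr initial learning rate.
#' @param momentum heavy-ball coefficient (0 disables momentum).
#' @param channels,seed passed to [init_toy_net()].
#' @param eps Dice-loss weight.
#' @param stop_ratio optional early-stop: end training once the loss falls
#'   below this fraction of its initial value (the trace is padded with the
#'   final value).
#' @return List with `net` (best iterate), `loss` (running-best trace,
#'   non-increasing), `loss_raw` (per-step values), `P` (probabilities of
#'   the best iterate, voxels x K), `classes` (the label coding).
#' @export
train_toy_network <- function(image, labels, steps = 500L, lr = 0.02,
                              momentum = 0.9, channels = 8L, seed = 1L,
                              eps = 1, stop_ratio = NULL) {
  cls <- sort(unique(as.vector(labels)))
  K <- length(cls)
  if (K < 2L) stop("train_toy_network: need at least 2 classes")
  Y <- matrix(0, length(labels), K)
  Y[cbind(seq_along(labels), match(as.vector(labels), cls))] <- 1
  net <- init_toy_net(channels = channels, classes = K, seed = seed)
  vel <- lapply(unclass(net), function(p) p * 0)
  trace <- numeric(steps + 1L)
  fw <- toy_forward(net, image, Y, eps = eps, with_cache = TRUE)
  trace[1] <- fw$loss
  best <- fw$loss
  best_net <- net
  best_P <- fw$P
  for (s in seq_len(steps)) {
    gr <- toy_backward(net, fw$cache, fw$P, Y, eps = eps)
    repeat {
      cand <- net
      vel_try <- vel
      for (nm in names(gr)) {
        vel_try[[nm]] <- momentum * vel[[nm]] - lr * gr[[nm]]
        cand[[nm]] <- cand[[nm]] + vel_try[[nm]]
      }
      fw_try <- toy_forward(cand, image, Y, eps = eps, with_cache = TRUE)
      if (is.finite(fw_try$loss) && fw_try$loss <= best * 1.05) {
        net <- cand
        vel <- vel_try
        fw <- fw_try
        lr <- lr * 1.05
        break
      }
      vel <- lapply(vel, function(p) p * 0)
      lr <- lr / 2
      if (lr < 1e-10) break
    }
    if (fw$loss < best) {
      best <- fw$loss
      best_net <- net
      best_P <- fw$P
    }
    trace[s + 1L] <- fw$loss
    if (lr < 1e-10 ||
        (!is.null(stop_ratio) && best < stop_ratio * trace[1])) {
      trace[(s + 1L):(steps + 1L)] <- fw$loss
      break
    }
  }
  list(net = best_net, loss = cummin(trace), loss_raw = trace,
       P = best_P, classes = cls)
}
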