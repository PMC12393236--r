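test_that("depthwise convolution: identity kernel, channel independence, hand sums", {
  set.seed(1)
  X <- array(rnorm(5 * 5 * 5 * 2), dim = c(5, 5, 5, 2))
  K1 <- array(0, dim = c(1, 1, 1, 2)); K1[1, 1, 1, ] <- 1
  expect_equal(dwconv(X, K1), X)
  K3 <- array(rnorm(27 * 2), dim = c(3, 3, 3, 2))
  Y <- dwconv(X, K3)
  ## channel independence: perturb channel 2, channel 1 output unchanged
  X2 <- X; X2[, , , 2] <- X2[, , , 2] + 1
  Y2 <- dwconv(X2, K3)
  expect_equal(Y2[, , , 1], Y[, , , 1])
  expect_false(isTRUE(all.equal(Y2[, , , 2], Y[, , , 2])))
  ## hand correlation sum at the center voxel of a 3^3 input
  Xs <- array(rnorm(27), dim = c(3, 3, 3, 1))
  Ks <- array(rnorm(27), dim = c(3, 3, 3, 1))
  hand <- 0
  for (u in -1:1) for (v in -1:1) for (w in -1:1) {
    hand <- hand + Xs[2 + u, 2 + v, 2 + w, 1] * Ks[u + 2, v + 2, w + 2, 1]
  }
  expect_equal(dwconv(Xs, Ks)[2, 2, 2, 1], hand)
  expect_error(dwconv(X, array(0, dim = c(3, 3, 3, 5))), "channel mismatch")
})

test_that("parameter counts match exhaustive enumeration of kernel banks", {
  expect_equal(unname(param_count(1, 1, 1)), c(2, 1))
  ## build the banks the printed formulas describe and count their entries
  c_in <- 16; c_out <- 32; k <- 3
  depthwise <- array(0, dim = c(k, k, c_in))          # k^2 per input channel
  pointwise <- array(0, dim = c(c_in, c_out))
  standard <- array(0, dim = c(k, k, c_in, c_out))
  pc <- param_count(c_in, c_out, k)
  expect_equal(unname(pc["p_sep"]), length(depthwise) + length(pointwise))
  expect_equal(unname(pc["p_std"]), length(standard))
  ## separable is smaller whenever both widths exceed one and k >= 2
  for (ci in c(2, 8)) for (co in c(2, 16)) for (kk in 2:4) {
    p <- param_count(ci, co, kk)
    expect_lt(p["p_sep"], p["p_std"])
  }
  ## cubic variant counts full 3D kernels
  pc3 <- param_count(c_in, c_out, k, cubic = TRUE)
  expect_equal(unname(pc3["p_std"]), c_in * c_out * k^3)
})

test_that("self-similarity mixing block follows its printed form", {
  ## single position: S = [[1]], F_out = 2 F'
  F1 <- matrix(c(0.3, -0.7), 1, 2)
  p <- list(W1 = matrix(0, 2, 2), b1 = c(0, 0), norm = "identity")
  r1 <- rvm_block(F1, p)
  expect_equal(r1$S, matrix(1, 1, 1))
  expect_equal(r1$out, 2 * r1$Fp)
  ## rows of S sum to 1
  set.seed(3)
  Fm <- matrix(rnorm(12), 4, 3)
  pm <- list(W1 = matrix(rnorm(9), 3, 3), b1 = rnorm(3), gamma = rep(1, 3),
             beta = rep(0, 3), norm = "layer")
  rm_ <- rvm_block(Fm, pm)
  expect_equal(rowSums(rm_$S), rep(1, 4), tolerance = 1e-9)
  ## 2 positions, d = 2, identity norm, zero projection: hand arithmetic
  F2 <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  r2 <- rvm_block(F2, list(W1 = matrix(0, 2, 2), b1 = c(0, 0), norm = "identity"))
  z <- F2 %*% t(F2) / sqrt(2)
  S_hand <- t(apply(z, 1, function(r) exp(r) / sum(exp(r))))
  expect_equal(r2$S, S_hand, tolerance = 1e-12)
  expect_equal(r2$out, F2 + S_hand %*% F2, tolerance = 1e-12)
})

test_that("decoder softmax normalizes and is shift-invariant", {
  z <- array(0, dim = c(3, 3, 3, 4))
  P <- decoder_softmax(z)
  expect_true(all(abs(P - 0.25) < 1e-12))
  set.seed(2)
  z <- array(rnorm(3 * 3 * 3 * 3), dim = c(3, 3, 3, 3))
  P <- decoder_softmax(z)
  sums <- apply(P, c(1, 2, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(decoder_softmax(z + 5), P, tolerance = 1e-9)
  ## hand 2-class logits (2, 0)
  z2 <- array(0, dim = c(1, 1, 1, 2)); z2[1, 1, 1, 1] <- 2
  P2 <- decoder_softmax(z2)
  expect_equal(P2[1, 1, 1, 1], exp(2) / (exp(2) + 1), tolerance = 1e-12)
  expect_error(decoder_softmax(array(0, dim = c(2, 2, 2, 1))), "K >= 2")
})

test_that("skip connections upsample and add", {
  lo <- array(rnorm(2 * 2 * 2 * 3), dim = c(2, 2, 2, 3))
  skip0 <- array(0, dim = c(4, 4, 4, 3))
  up <- skip_add(lo, skip0)
  expect_equal(dim(up), c(4, 4, 4, 3))
  ## constants stay constant under the interpolation
  const <- array(2.5, dim = c(2, 2, 2, 1))
  expect_true(all(abs(skip_add(const, array(0, dim = c(4, 4, 4, 1))) - 2.5) < 1e-12))
  ## already at target size: plain elementwise sum
  a <- array(rnorm(4 * 4 * 4 * 2), dim = c(4, 4, 4, 2))
  b <- array(rnorm(4 * 4 * 4 * 2), dim = c(4, 4, 4, 2))
  expect_equal(skip_add(a, b), a + b)
})

test_that("hybrid loss evaluates its printed decomposition", {
  ## exactly correct one-hot prediction: zero loss
  Y <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(as.numeric(hybrid_loss(Y, Y)), 0, tolerance = 1e-6)
  ## eps = 0 reduces to cross-entropy
  P <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, 2, byrow = TRUE)
  Yt <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  expect_equal(as.numeric(hybrid_loss(P, Yt, eps = 0)),
               -mean(log(c(0.7, 0.6))), tolerance = 1e-12)
  ## uniform prediction over K=2 on one voxel: CE = ln 2; Dice terms 2/3, 0
  Pu <- matrix(0.5, 1, 2); Yu <- matrix(c(1, 0), 1, 2)
  l <- hybrid_loss(Pu, Yu, eps = 1)
  expect_equal(attr(l, "ce"), log(2), tolerance = 1e-12)
  expect_equal(attr(l, "dice_loss"), 1 - mean(c(2 * 0.5 / 1.5, 0)), tolerance = 1e-12)
  expect_error(hybrid_loss(matrix(c(0.5, 0.2), 1, 2), Yu), "sum to 1")
})

test_that("analytic gradients of the toy network match finite differences", {
  set.seed(9)
  n <- 4L
  x <- array(rnorm(n^3), dim = rep(n, 3))
  labels <- array(sample(0:1, n^3, replace = TRUE), dim = rep(n, 3))
  cls <- sort(unique(as.vector(labels)))
  Y <- matrix(0, n^3, length(cls))
  Y[cbind(seq_len(n^3), match(as.vector(labels), cls))] <- 1
  net <- init_toy_net(channels = 2L, classes = 2L, seed = 3)
  fw <- svfatlas:::toy_forward(net, x, Y, with_cache = TRUE)
  gr <- svfatlas:::toy_backward(net, fw$cache, fw$P, Y)
  h <- 1e-5
  for (nm in c("We", "K1", "gamma", "W1", "b1", "K2", "b2", "Wh", "bh")) {
    idx <- sample(length(net[[nm]]), min(3, length(net[[nm]])))
    for (i in idx) {
      np <- net; np[[nm]][i] <- np[[nm]][i] + h
      nm_ <- net; nm_[[nm]][i] <- nm_[[nm]][i] - h
      fd <- (svfatlas:::toy_forward(np, x, Y)$loss -
             svfatlas:::toy_forward(nm_, x, Y)$loss) / (2 * h)
      expect_equal(gr[[nm]][i], fd, tolerance = 1e-4)
    }
  }
})

test_that("toy network training reduces the hybrid loss on a small phantom", {
  p <- phantom_params(grid_shape = c(8, 8, 8), noise_sd = 0)
  ph <- make_phantom(26, p)
  labels <- (ph$labels$labels > 0) * 1L   # binary: background vs tissue
  fit <- train_toy_network(ph$subject$image$values, labels, steps = 120,
                           channels = 4L, seed = 1)
  expect_lt(fit$loss[length(fit$loss)], 0.5 * fit$loss[1])
  expect_true(all(is.finite(fit$loss)))
  expect_equal(toy_net_params(fit$net),
               sum(sapply(unclass(fit$net), length)))
})
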