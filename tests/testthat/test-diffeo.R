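test_that("exp of the zero field is exactly the identity", {
  shape <- c(8, 10, 12)
  m <- exp_svf(zero_svf(shape))
  expect_true(all(m$displacement == 0))
  expect_identical(m$svf$vectors, zero_svf(shape)$vectors)
})

test_that("a constant field integrates to a pure translation", {
  v <- const_svf(c(12, 12, 12), c(1.7, -0.9, 0.4))
  m <- exp_svf(v)
  expect_equal(max(abs(m$displacement[, , , 1] - 1.7)), 0, tolerance = 1e-10)
  expect_equal(max(abs(m$displacement[, , , 2] + 0.9)), 0, tolerance = 1e-10)
  expect_equal(max(abs(m$displacement[, , , 3] - 0.4)), 0, tolerance = 1e-10)
})

test_that("exp_svf rejects non-finite fields", {
  arr <- array(0, dim = c(4, 4, 4, 3))
  arr[1] <- NA
  expect_error(velocity_field(arr), "non-finite")
})

test_that("exp_svf agrees with a many-step Euler flow oracle", {
  shape <- c(32, 32, 32)
  v <- random_svf(shape, max_norm = 2, seed = 11)
  m <- exp_svf(v)
  pts <- expand.grid(x = seq(5, 28, by = 3), y = seq(5, 28, by = 3),
                     z = seq(5, 28, by = 3))
  endpoints <- euler_flow(v, pts, nstep = 800)
  err <- sqrt(rowSums((diffeo_endpoints(m, pts) - endpoints)^2))
  expect_lt(median(err), 1e-3)
})

test_that("negated field inverts the exponential", {
  expect_true(all(invert_svf(zero_svf(c(4, 4, 4)))$vectors == 0))
  v <- const_svf(c(6, 6, 6), c(0.5, -1, 0.25))
  expect_equal(invert_svf(v)$vectors, -v$vectors)
  shape <- c(24, 24, 24)
  for (seed in c(3, 4)) {
    v <- random_svf(shape, max_norm = 2, seed = seed)
    resid <- compose_diffeo(exp_svf(v), exp_svf(invert_svf(v)))
    expect_lt(svfatlas:::max_vec_norm(resid$displacement), 0.1)
  }
})

test_that("Jacobian determinant of exp stays positive for smooth fields", {
  for (seed in c(2, 9)) {
    v <- random_svf(c(24, 24, 24), max_norm = 2, seed = seed)
    expect_gt(min(jacobian_det(exp_svf(v))), 0)
  }
})

test_that("BCH with a zero field returns the other operand exactly", {
  shape <- c(10, 10, 10)
  v <- random_svf(shape, max_norm = 1, seed = 5)
  z <- zero_svf(shape)
  expect_equal(compose_bch(v, z, order = 2)$vectors, v$vectors)
  expect_equal(compose_bch(z, v, order = 2)$vectors, v$vectors)
})

test_that("commuting (constant) fields compose additively at any order", {
  v <- const_svf(c(8, 8, 8), c(0.3, 0.1, -0.2))
  w <- const_svf(c(8, 8, 8), c(-0.1, 0.4, 0.15))
  for (ord in 1:2) {
    expect_equal(compose_bch(v, w, order = ord)$vectors, v$vectors + w$vectors)
  }
})

test_that("order-2 BCH beats order-1 against dense composition", {
  shape <- c(16, 16, 16)
  errs <- sapply(c(21, 22, 23), function(seed) {
    v <- random_svf(shape, max_norm = 1, seed = seed)
    w <- random_svf(shape, max_norm = 1, seed = seed + 100)
    dense <- compose_diffeo(exp_svf(v), exp_svf(w))
    per_order <- sapply(1:2, function(ord) {
      approx <- exp_svf(compose_bch(v, w, order = ord))
      d <- approx$displacement - dense$displacement
      median(sqrt(d[, , , 1]^2 + d[, , , 2]^2 + d[, , , 3]^2))
    })
    expect_lt(per_order[2], per_order[1])
    per_order[2]
  })
  expect_true(all(errs <= 0.05))
})

test_that("BCH rejects mismatched grids", {
  expect_error(compose_bch(zero_svf(c(8, 8, 8)), zero_svf(c(8, 8, 9))),
               "incompatible grids")
})

test_that("Log-Euclidean mean of coinciding fields is exp(-v)", {
  v <- random_svf(c(12, 12, 12), max_norm = 1, seed = 8)
  m <- log_euclidean_mean_inverse(list(v, v, v), c(0.2, 0.5, 0.3))
  ref <- exp_svf(invert_svf(v))
  expect_equal(m$displacement, ref$displacement, tolerance = 1e-10)
})

test_that("Log-Euclidean mean of an antisymmetric pair is the identity", {
  v <- random_svf(c(12, 12, 12), max_norm = 1.5, seed = 14)
  m <- log_euclidean_mean_inverse(list(v, invert_svf(v)), c(0.5, 0.5))
  expect_true(all(m$displacement == 0))
})

test_that("Log-Euclidean mean of constant fields is the negated weighted translation", {
  shape <- c(8, 8, 8)
  v1 <- const_svf(shape, c(1, 0, 0))
  v2 <- const_svf(shape, c(0, 2, 0))
  v3 <- const_svf(shape, c(0, 0, -1))
  m <- log_euclidean_mean_inverse(list(v1, v2, v3), c(0.2, 0.3, 0.5))
  expected <- -(0.2 * c(1, 0, 0) + 0.3 * c(0, 2, 0) + 0.5 * c(0, 0, -1))
  for (c in 1:3) {
    expect_equal(max(abs(m$displacement[, , , c] - expected[c])), 0, tolerance = 1e-10)
  }
})

test_that("Log-Euclidean mean is permutation-invariant and validates weights", {
  shape <- c(10, 10, 10)
  vs <- lapply(1:3, function(s) random_svf(shape, max_norm = 0.8, seed = s))
  ws <- c(0.5, 0.2, 0.3)
  perm <- c(3, 1, 2)
  m1 <- log_euclidean_mean_inverse(vs, ws)
  m2 <- log_euclidean_mean_inverse(vs[perm], ws[perm])
  expect_equal(m1$displacement, m2$displacement, tolerance = 1e-12)
  expect_error(log_euclidean_mean_inverse(vs, c(0.5, 0.2, 0.2)), "invalid weights")
  expect_error(log_euclidean_mean_inverse(vs, c(-0.1, 0.6, 0.5)), "invalid weights")
})

test_that("warping through the identity is exact", {
  ph <- tiny_phantom(12)
  id <- identity_diffeo(c(12, 12, 12))
  expect_identical(warp(ph$subject$image, id, mode = "nearest")$values,
                   ph$subject$image$values)
  expect_identical(warp(ph$labels, id)$labels, ph$labels$labels)
})

test_that("integer translations index-shift images under nearest resampling", {
  arr <- array(seq_len(6^3), dim = c(6, 6, 6))
  img <- image3d(arr)
  m <- diffeo(const_svf(c(6, 6, 6), c(2, 0, 0))$vectors)
  out <- warp(img, m, mode = "nearest")
  expect_equal(out$values[1:4, , ], arr[3:6, , ])
  expect_true(all(out$values[5:6, , ] == 0))  # out-of-domain fill
})

test_that("warp round trip through exp(v), exp(-v) has small intensity error", {
  ph <- tiny_phantom(16, noise_sd = 0)
  v <- random_svf(c(16, 16, 16), max_norm = 1.5, seed = 6)
  once <- warp(ph$subject$image, exp_svf(v))
  back <- warp(once, exp_svf(invert_svf(v)))
  round_trip_mae <- mean(abs(back$values - ph$subject$image$values))
  expect_lt(round_trip_mae, 0.05)
  expect_error(warp(ph$subject$image, identity_diffeo(c(8, 8, 8))), "incompatible grids")
})
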