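test_that("label propagation is exact for identity and integer shifts", {
  ph <- tiny_phantom(16)
  expect_identical(propagate(ph$labels, identity_diffeo(c(16, 16, 16)))$labels,
                   ph$labels$labels)
  m <- diffeo(const_svf(c(16, 16, 16), c(0, 3, 0))$vectors)
  shifted <- propagate(ph$labels, m)
  expect_equal(shifted$labels[, 1:13, ], ph$labels$labels[, 4:16, ])
})

test_that("labels survive a smooth warp round trip with high overlap", {
  ph <- tiny_phantom(24)
  v <- random_svf(c(24, 24, 24), max_norm = 2, seed = 3)
  fwd <- propagate(ph$labels, exp_svf(v))
  back <- propagate(fwd, exp_svf(invert_svf(v)))
  ## large (bulky) labels survive; thin ribbons erode under nearest-neighbor
  expect_gt(sum(ph$labels$labels == 1), 500)
  expect_gte(dice(back, ph$labels, 1), 0.95)
})

test_that("unanimous raters are reproduced with degenerate posteriors", {
  ph <- tiny_phantom(12)
  fit <- staple_fuse(list(ph$labels, ph$labels, ph$labels))
  expect_identical(fit$consensus$labels, ph$labels$labels)
  expect_true(all(apply(fit$posterior, 1, max) >= 1 - 1e-4))
  ## without the confusion-matrix regularization the diagonals reach 1 exactly
  fit0 <- staple_fuse(list(ph$labels, ph$labels, ph$labels), theta_prior_count = 0)
  expect_identical(fit0$consensus$labels, ph$labels$labels)
  for (th in fit0$theta) expect_true(all(diag(th) > 1 - 1e-4))
})

test_that("majority vote wins on a 2-vs-1 disagreement block", {
  base <- array(1L, dim = c(8, 8, 8))
  r1 <- base; r2 <- base; r3 <- base
  r3[3:5, 3:5, 3:5] <- 2L              # one dissenter on a block
  fit <- staple_fuse(list(labelmap3d(r1), labelmap3d(r2), labelmap3d(r3)),
                     prior = "uniform")
  expect_true(all(fit$consensus$labels == 1L))
})

test_that("STAPLE log-likelihood is monotone non-decreasing", {
  ph <- tiny_phantom(16)
  labs <- sort(unique(as.vector(ph$labels$labels)))
  L <- length(labs)
  th <- matrix(0.15 / (L - 1), L, L); diag(th) <- 0.85
  raters <- simulate_raters(ph$labels, replicate(3, th, simplify = FALSE), seed = 2)
  fit <- staple_fuse(raters)
  expect_true(all(diff(fit$loglik) >= -1e-6 * abs(fit$loglik[1])))
})

test_that("STAPLE is invariant to rater permutation", {
  ph <- tiny_phantom(12)
  labs <- sort(unique(as.vector(ph$labels$labels)))
  L <- length(labs)
  ths <- lapply(c(0.95, 0.85, 0.75), function(dg) {
    th <- matrix((1 - dg) / (L - 1), L, L); diag(th) <- dg; th
  })
  raters <- simulate_raters(ph$labels, ths, seed = 4)
  f1 <- staple_fuse(raters)
  f2 <- staple_fuse(raters[c(3, 1, 2)])
  expect_identical(f1$consensus$labels, f2$consensus$labels)
  expect_equal(f1$theta[[1]], f2$theta[[2]], tolerance = 1e-10)
})

test_that("confusion-matrix recovery improves with voxel count", {
  err_at <- function(grid) {
    ph <- make_phantom(28, phantom_params(grid_shape = rep(grid, 3)), seed = 1)
    labs <- sort(unique(as.vector(ph$labels$labels)))
    L <- length(labs)
    ths <- lapply(c(0.95, 0.85, 0.75), function(dg) {
      th <- matrix((1 - dg) / (L - 1), L, L); diag(th) <- dg; th
    })
    raters <- simulate_raters(ph$labels, ths, seed = 6)
    fit <- staple_fuse(raters)
    mean(sapply(1:3, function(j) mean(abs(diag(fit$theta[[j]]) - diag(ths[[j]])))))
  }
  expect_lt(err_at(32), err_at(16))
})

test_that("staple_fuse validates its inputs", {
  ph <- tiny_phantom(8)
  expect_error(staple_fuse(list(ph$labels)), "at least 2")
})

test_that("multi-atlas segmentation with the query as its own atlas is exact", {
  ph <- tiny_phantom(16, age = 26)
  tp <- atlas_timepoint(26, ph$subject$image,
                        identity_diffeo(c(16, 16, 16)), iteration = 1L)
  bank <- list(list(timepoint = tp, labels = ph$labels))
  res <- mas_segment(ph$subject, bank,
                     config = reg_config(levels = 1, iters_per_level = 5))
  expect_identical(res$labels$labels, ph$labels$labels)
})

test_that("atlases outside the age window are rejected with a clear error", {
  ph <- tiny_phantom(16, age = 26)
  mk <- function(t) list(timepoint = atlas_timepoint(t, ph$subject$image,
                                                     identity_diffeo(c(16, 16, 16)), 1L),
                         labels = ph$labels)
  expect_error(mas_segment(ph$subject, list(mk(24), mk(28))),
               "no atlas within 1 week")
  ## exactly at the window edge the atlas is kept
  res <- mas_segment(ph$subject, list(mk(25)),
                     config = reg_config(levels = 1, iters_per_level = 2))
  expect_s3_class(res, "mas_result")
})
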