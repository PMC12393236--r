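test_that("dice matches its formula on hand cases", {
  a <- array(0L, dim = c(6, 6, 6)); b <- a
  a[1:2, 1, 1] <- 1L; b[2:3, 1, 1] <- 1L       # |A|=|B|=2, one shared
  expect_equal(dice(labelmap3d(a), labelmap3d(b), 1), 0.5)
  m <- labelmap3d(a)
  expect_equal(dice(m, m, 1), 1)
  disj <- array(0L, dim = c(6, 6, 6)); disj[5, 5, 5] <- 1L
  expect_equal(dice(m, labelmap3d(disj), 1), 0)
  expect_message(val <- dice(m, m, 7), "absent")
  expect_equal(val, 1)
})

test_that("hausdorff is zero on identity and equals the shift for translations", {
  a <- array(0L, dim = c(12, 12, 12))
  a[3:5, 3:5, 3:5] <- 1L
  b <- array(0L, dim = c(12, 12, 12))
  b[6:8, 3:5, 3:5] <- 1L                        # 3-voxel axial shift
  A <- labelmap3d(a); B <- labelmap3d(b)
  expect_equal(hausdorff(A, A, 1), 0)
  expect_equal(hausdorff(A, B, 1), 3)
  expect_equal(hausdorff(A, B, 1), hausdorff(B, A, 1))
  expect_error(hausdorff(A, labelmap3d(array(0L, dim = c(12, 12, 12))), 1),
               "undefined")
})

test_that("hausdorff matches the brute-force all-pairs oracle on sparse sets", {
  for (seed in c(1, 2, 3)) {
    A <- random_voxel_set_map(40, c(12, 12, 12), seed = seed)
    B <- random_voxel_set_map(50, c(12, 12, 12), seed = seed + 50)
    oracle <- brute_hausdorff(mask_coords(A, 1), mask_coords(B, 1))
    expect_equal(hausdorff(A, B, 1), oracle, tolerance = 1e-12)
    o95 <- brute_hausdorff(mask_coords(A, 1), mask_coords(B, 1), percentile = 95)
    expect_equal(hausdorff(A, B, 1, percentile = 95), o95, tolerance = 1e-12)
  }
})

test_that("dice and hausdorff are symmetric and flip-invariant", {
  ph <- tiny_phantom(16)
  w <- warp(ph$labels, exp_svf(random_svf(c(16, 16, 16), max_norm = 1, seed = 4)))
  expect_equal(dice(ph$labels, w, 1), dice(w, ph$labels, 1))
  flip <- function(m) labelmap3d(m$labels[16:1, , ])
  expect_equal(dice(flip(ph$labels), flip(w), 1), dice(ph$labels, w, 1))
  expect_equal(hausdorff(flip(ph$labels), flip(w), 1), hausdorff(ph$labels, w, 1))
})

test_that("edge sharpness of an ideal step is the central-difference value", {
  arr <- array(0, dim = c(12, 12, 12))
  arr[7:12, , ] <- 1
  expect_equal(edge_sharpness(image3d(arr)), 0.5)
  ## translation invariance
  arr2 <- array(0, dim = c(12, 12, 12)); arr2[5:12, , ] <- 1
  expect_equal(edge_sharpness(image3d(arr2)), 0.5)
  expect_error(edge_sharpness(image3d(array(1, dim = c(8, 8, 8)))), "constant")
})

test_that("blurring strictly reduces edge sharpness", {
  ph <- tiny_phantom(24, noise_sd = 0)
  img <- ph$subject$image
  s0 <- edge_sharpness(img)
  prev <- s0
  for (sg in c(0.8, 1.5, 2.5)) {
    blurred <- image3d(svfatlas:::gaussian_smooth3(img$values, sg))
    s <- edge_sharpness(blurred)
    expect_lt(s, prev)
    prev <- s
  }
})

test_that("metric reports aggregate per-label values", {
  ph <- tiny_phantom(16)
  rep0 <- report(ph$labels, ph$labels)
  expect_true(all(rep0$per_label$dice == 1))
  expect_true(all(rep0$per_label$hd == 0))
  ## 3-label toy with hand-computed mean
  a <- array(0L, dim = c(8, 8, 8)); a[2:3, 2, 2] <- 1L; a[5, 5, 5] <- 2L; a[7, 7, 7] <- 3L
  b <- a; b[3, 2, 2] <- 0L                       # label 1 loses a voxel
  rp <- report(labelmap3d(b), labelmap3d(a))
  d1 <- 2 * 1 / (1 + 2)
  expect_equal(rp$per_label$dice, c(d1, 1, 1))
  expect_equal(rp$summary$mean[rp$summary$metric == "dice"], mean(c(d1, 1, 1)))
  csv <- tempfile(fileext = ".csv")
  write_report_csv(rp, csv)
  expect_equal(nrow(utils::read.csv(csv)), 3)
})
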