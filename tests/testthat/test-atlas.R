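test_that("global normalization maps the robust range onto [0, 1]", {
  ph <- tiny_phantom(16)
  n1 <- normalize_global(ph$subject$image)
  q <- quantile(n1$values, c(0.01, 0.99), type = 7)
  expect_equal(unname(q), c(0, 1), tolerance = 1e-9)
  ## affine invariance: scaling the input changes nothing
  n2 <- normalize_global(image3d(ph$subject$image$values * 10))
  expect_equal(n1$values, n2$values, tolerance = 1e-9)
  ## already-normalized image is a fixed point
  n3 <- normalize_global(n1)
  expect_equal(n3$values, n1$values, tolerance = 1e-12)
  expect_error(normalize_global(image3d(array(1, dim = c(4, 4, 4)))), "degenerate")
})

test_that("reference normalization matches median and IQR", {
  ph <- tiny_phantom(16, seed = 1)
  ref <- tiny_phantom(16, seed = 2)
  out <- normalize_global(ph$subject$image, reference = ref$subject$image)
  expect_equal(median(out$values), median(ref$subject$image$values), tolerance = 1e-9)
  expect_equal(IQR(out$values), IQR(ref$subject$image$values), tolerance = 1e-9)
})

test_that("template building averages warped images with kernel weights", {
  ph <- tiny_phantom(12)
  subs <- list(ph$subject, ph$subject, ph$subject)
  w <- compute_weights(c(26, 26, 26), t = 26, sigma = 0.5)
  tmpl <- build_template(subs, NULL, w)
  expect_equal(tmpl$values, ph$subject$image$values, tolerance = 1e-12)
  ## weights (1, 0): only the first subject contributes
  other <- subject("b", image3d(ph$subject$image$values * 0 + 0.3), 26)
  w10 <- compute_weights(c(26, 28.5), t = 26, sigma = 0.5)
  tmpl2 <- build_template(list(ph$subject, other), NULL, w10)
  expect_equal(tmpl2$values, ph$subject$image$values, tolerance = 1e-12)
  ## constant images: plain weighted arithmetic
  c1 <- subject("c1", image3d(array(0.2, dim = c(4, 4, 4))), 25)
  c2 <- subject("c2", image3d(array(0.8, dim = c(4, 4, 4))), 25.4)
  wts <- structure(list(weights = c(0.25, 0.75), t = 25.2, sigma = 0.5,
                        support = 1:2), class = "kernel_weights")
  tmpl3 <- build_template(list(c1, c2), NULL, wts)
  expect_equal(unique(as.vector(tmpl3$values)), 0.65, tolerance = 1e-12)
  expect_error(build_template(list(c1), NULL, wts), "mismatch")
})

test_that("longitudinal maps start at the identity and cancel at the subject age", {
  shape <- c(8, 8, 8)
  psi0 <- update_longitudinal_maps(list(), subject_age = 26, target_ages = c(25, 27))
  expect_true(all(vapply(psi0, is.null, logical(1))))
  ## constant-field history: psi is a translation by the field differences
  h <- list(
    list(`25.0000` = const_svf(shape, c(0.3, 0, 0)),
         `26.0000` = const_svf(shape, c(0.1, 0, 0))),
    list(`25.0000` = const_svf(shape, c(0.2, 0, 0)),
         `26.0000` = const_svf(shape, c(0.05, 0, 0)))
  )
  psi <- update_longitudinal_maps(h, subject_age = 26, target_ages = c(25, 26))
  ## at t = t_i the products cancel exactly
  expect_lt(svfatlas:::max_vec_norm(psi[["26.0000"]]$displacement), 1e-10)
  ## constant fields commute: log psi = (0.3 + 0.2) - (0.1 + 0.05)
  expect_equal(mean(psi[["25.0000"]]$displacement[, , , 1]), 0.35, tolerance = 1e-10)
  expect_error(update_longitudinal_maps(list(list(`25.0000` = NULL)), 25, 25),
               "missing residual SVF")
})

test_that("residual deformation averages the age-specific logs", {
  v <- random_svf(c(8, 8, 8), max_norm = 1, seed = 2)
  r <- residual_deformation(list(v, v), c(0.5, 0.5))
  expect_equal(r$displacement, exp_svf(invert_svf(v))$displacement, tolerance = 1e-12)
  r2 <- residual_deformation(list(v, invert_svf(v)), c(0.5, 0.5))
  expect_true(all(r2$displacement == 0))
})

test_that("an identical-input cohort is a fixed point of atlas construction", {
  ph <- tiny_phantom(16, age = 26, noise_sd = 0)
  cohort <- lapply(1:5, function(i) list(subject = subject(paste0("s", i),
                                                           ph$subject$image, 26),
                                         labels = ph$labels))
  atlas <- build_atlas(cohort, target_ages = 26, n_iter = 2,
                       config = reg_config(similarity = "ssd",
                                           iters_per_level = 10))
  tp <- atlas$timepoints[["26.0000"]]
  ref <- normalize_global(ph$subject$image)
  expect_lt(mean(abs(tp$template$values - ref$values)), 1e-6)
  for (tr in atlas$transforms) {
    expect_lt(svfatlas:::max_vec_norm(tr$log_phi$vectors), 0.05)
  }
  expect_false(is.null(tp$residual$svf))
})

test_that("atlas drift decreases over iterations on a jittered cohort", {
  p <- phantom_params(grid_shape = c(24, 24, 24))
  cohort <- make_cohort(6, params = p, seed = 3, ages = rep(c(25, 26), each = 3))
  atlas <- build_atlas(cohort, target_ages = c(25, 26), n_iter = 2,
                       config = reg_config(similarity = "ssd",
                                           iters_per_level = c(40, 30, 20)))
  dg <- atlas$diagnostics
  for (t in c(25, 26)) {
    d1 <- dg$drift[dg$iteration == 1 & dg$age == t]
    d2 <- dg$drift[dg$iteration == 2 & dg$age == t]
    expect_lt(d2, d1)
  }
})

test_that("unsupported target ages raise a named error", {
  ph <- tiny_phantom(12, age = 26)
  cohort <- list(list(subject = ph$subject, labels = ph$labels))
  expect_error(build_atlas(cohort, target_ages = 30, n_iter = 1), "30")
})
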