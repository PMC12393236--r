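#' Exponential of a stationary velocity field by scaling and squaring
#'
#' Integrates the flow of a stationary velocity field to obtain a dense
#' diffeomorphic displacement map. The field is divided by `2^N`, with `N`
#' the smallest number of squarings such that the scaled field's maximum
#' displacement is at most `max_step` voxels (capped at `max_squarings`),
#' and the small deformation is then composed with itself `N` times.
#' The returned map stores `v` as its generating SVF.
#'
#' The small deformation is initialized at second order,
#' `h v + (h^2/2) (Jv) v` with `h = 1/2^N`, so the endpoint error of smooth
#' compact-support fields stays well below a hundredth of a voxel under the
#' default policy (scaled step at most 1/4 voxel, cubic Catmull-Rom
#' resampling in the squaring recursion); `interp = "linear"` is the faster
#' variant used inside iterative registration.
#'
#' @param v a [velocity_field()].
#' @param max_step maximum displacement (voxels) of the scaled field;
#'   default 0.25.
#' @param max_squarings cap on the number of squaring steps; default 12.
#' @param interp `"cubic"` (default) or `"linear"` resampling during
#'   squaring.
#' @param second_order include the second-order term in the initial small
#'   step (disable only where speed matters more than accuracy).
#' @return A [diffeo()] carrying `v` in `$svf`.
#' @export
exp_svf <- function(v, max_step = 0.25, max_squarings = 12L,
                    interp = c("cubic", "linear"), second_order = TRUE) {
  if (!inherits(v, "velocity_field")) stop("exp_svf: `v` must be a velocity_field")
  interp <- match.arg(interp)
  vec <- v$vectors
  mx <- max_vec_norm(vec)
  n_sq <- if (mx <= max_step) 0L else min(max_squarings, ceiling(log2(mx / max_step)))
  h <- 1 / 2^n_sq
  disp <- h * vec
  if (second_order) {
    ## second-order initial step: h v + (h^2/2) (Jv) v
    adv <- array(0, dim = dim(vec))
    for (c in 1:3) {
      g <- gradient3(vec[, , , c])
      adv[, , , c] <- g$gx * vec[, , , 1] + g$gy * vec[, , , 2] + g$gz * vec[, , , 3]
    }
    disp <- disp + (h^2 / 2) * adv
  }
  if (n_sq > 0L) {
    shape <- dim(vec)[1:3]
    g <- grid_coords(shape)
    for (s in seq_len(n_sq)) {
      ci <- g$x + disp[, , , 1]
      cj <- g$y + disp[, , , 2]
      ck <- g$z + disp[, , , 3]
      disp <- disp + sample_field(disp, ci, cj, ck, extrap = "clamp", mode = interp)
    }
  }
  diffeo(disp, spacing = v$spacing, origin = v$origin, svf = v)
}

#' Invert a stationary velocity field
#'
#' In the stationary-velocity parameterization the group inverse is the field
#' negation: `exp(-v)` approximates `exp(v)^{-1}`.
#'
#' @param v a [velocity_field()].
#' @return The negated [velocity_field()].
#' @export
invert_svf <- function(v) {
  if (!inherits(v, "velocity_field")) stop("invert_svf: `v` must be a velocity_field")
  velocity_field(-v$vectors, spacing = v$spacing, origin = v$origin)
}

#' Compose two velocity fields with the Baker-Campbell-Hausdorff expansion
#'
#' Approximates `log(exp(v) o exp(w))`. Order 1 returns `v + w`; order 2 adds
#' half the Lie bracket, `v + w + [v, w] / 2`, with
#' `[v, w] = Jv %*% w - Jw %*% v` evaluated with central-difference Jacobians
#' (one-sided at the grid faces).
#'
#' @param v,w [velocity_field()]s on the same grid.
#' @param order truncation order, 1 or 2 (default 2).
#' @return A [velocity_field()] approximating the log of the composition.
#' @export
compose_bch <- function(v, w, order = 2L) {
  check_same_grid(v, w, "velocity fields")
  if (!order %in% c(1L, 2L)) stop("compose_bch: order must be 1 or 2")
  out <- v$vectors + w$vectors
  if (order == 2L) out <- out + 0.5 * lie_bracket(v$vectors, w$vectors)
  velocity_field(out, spacing = v$spacing, origin = v$origin)
}

## [v,w]_c = sum_a dv_c/dx_a * w_a - dw_c/dx_a * v_a  (voxel units)
lie_bracket <- function(v, w) {
  out <- array(0, dim = dim(v))
  for (c in 1:3) {
    gv <- gradient3(v[, , , c])
    gw <- gradient3(w[, , , c])
    out[, , , c] <- gv$gx * w[, , , 1] + gv$gy * w[, , , 2] + gv$gz * w[, , , 3] -
      gw$gx * v[, , , 1] - gw$gy * v[, , , 2] - gw$gz * v[, , , 3]
  }
  out
}

## Dense composition of two displacement fields: (A o B)(x) = x + dB(x) + dA(x + dB(x)).
compose_disp <- function(da, db, mode = "cubic") {
  shape <- dim(da)[1:3]
  g <- grid_coords(shape)
  ci <- g$x + db[, , , 1]
  cj <- g$y + db[, , , 2]
  ck <- g$z + db[, , , 3]
  db + sample_field(da, ci, cj, ck, extrap = "clamp", mode = mode)
}

#' Dense composition of two diffeomorphic maps
#'
#' Returns the map `a o b` as a dense displacement field, by resampling `a`'s
#' displacement at the points displaced by `b`. Used as the reference
#' ("ground-truth composition") against which BCH approximations are measured;
#' the result carries no SVF.
#'
#' @param a,b [diffeo()]s on the same grid.
#' @param interp `"cubic"` (default) or `"linear"` resampling of `a`'s
#'   displacement.
#' @return A [diffeo()] without an SVF.
#' @export
compose_diffeo <- function(a, b, interp = c("cubic", "linear")) {
  interp <- match.arg(interp)
  check_same_grid(a, b, "diffeos")
  diffeo(compose_disp(a$displacement, b$displacement, mode = interp),
         spacing = a$spacing, origin = a$origin)
}

#' Weighted Log-Euclidean mean of inverse transformations
#'
#' Averages diffeomorphisms through their logarithms: given velocity fields
#' `v_i` (the logs of forward maps) and weights `w_i`, returns
#' `exp(-sum_i w_i v_i)` — the Log-Euclidean mean of the inverse maps. This is
#' the residual-deformation estimator used to re-center the atlas.
#'
#' @param vs list of [velocity_field()]s on one grid.
#' @param ws numeric weights, nonnegative, summing to 1 within 1e-10.
#' @return A [diffeo()] carrying its generating SVF.
#' @export
log_euclidean_mean_inverse <- function(vs, ws) {
  if (length(vs) == 0L) stop("log_euclidean_mean_inverse: empty field list")
  if (length(vs) != length(ws)) stop("log_euclidean_mean_inverse: fields and weights differ in length")
  if (any(ws < 0)) stop("invalid weights: must be nonnegative")
  if (abs(sum(ws) - 1) > 1e-10) stop("invalid weights: must sum to 1 (got ", sum(ws), ")")
  ref <- vs[[1]]
  acc <- array(0, dim = dim(ref$vectors))
  for (i in seq_along(vs)) {
    check_same_grid(ref, vs[[i]], "velocity fields")
    if (ws[i] != 0) acc <- acc + ws[i] * vs[[i]]$vectors
  }
  exp_svf(velocity_field(-acc, spacing = ref$spacing, origin = ref$origin))
}

#' Warp an image or label map through a diffeomorphic map
#'
#' Pullback resampling: `out(x) = image(x + displacement(x))`. Intensity
#' images use trilinear interpolation by default; label maps always use
#' nearest-neighbor. Samples falling outside the domain take `fill`
#' (default 0).
#'
#' @param image an [image3d()] or [labelmap3d()].
#' @param map a [diffeo()] on the same grid.
#' @param mode `"linear"` or `"nearest"`; label maps force `"nearest"`.
#' @param fill out-of-domain constant.
#' @return An object of the same class as `image`.
#' @export
warp <- function(image, map, mode = c("linear", "nearest"), fill = 0) {
  mode <- match.arg(mode)
  check_same_grid(image, map, "image and map")
  shape <- grid_shape(image)
  g <- grid_coords(shape)
  d <- map$displacement
  ci <- g$x + d[, , , 1]; cj <- g$y + d[, , , 2]; ck <- g$z + d[, , , 3]
  if (inherits(image, "labelmap3d")) {
    out <- interp3(image$labels, ci, cj, ck, mode = "nearest", extrap = "fill", fill = fill)
    dim(out) <- shape
    return(labelmap3d(out, spacing = image$spacing, origin = image$origin, key = image$key))
  }
  out <- interp3(image$values, ci, cj, ck, mode = mode, extrap = "fill", fill = fill)
  dim(out) <- shape
  image3d(out, spacing = image$spacing, origin = image$origin)
}

#' Jacobian determinant of a deformation
#'
#' Determinant of the Jacobian of `Id + displacement` at every voxel
#' (central differences, one-sided at the faces). Strictly positive values
#' certify local invertibility (preservation of topology).
#'
#' @param map a [diffeo()].
#' @return A numeric 3D array of determinants.
#' @export
jacobian_det <- function(map) {
  d <- map$displacement
  J <- vector("list", 3)
  for (c in 1:3) J[[c]] <- gradient3(d[, , , c])
  a11 <- 1 + J[[1]]$gx; a12 <- J[[1]]$gy; a13 <- J[[1]]$gz
  a21 <- J[[2]]$gx; a22 <- 1 + J[[2]]$gy; a23 <- J[[2]]$gz
  a31 <- J[[3]]$gx; a32 <- J[[3]]$gy; a33 <- 1 + J[[3]]$gz
  a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
}

#' Identity map on a grid
#'
#' @param shape integer length-3 voxel counts.
#' @param spacing,origin grid geometry.
#' @return A [diffeo()] with zero displacement carrying the zero SVF.
#' @export
identity_diffeo <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  z <- array(0, dim = c(shape, 3))
  diffeo(z, spacing = spacing, origin = origin,
         svf = velocity_field(z, spacing = spacing, origin = origin))
}

#' Zero velocity field on a grid
#'
#' @inheritParams identity_diffeo
#' @return A [velocity_field()] of zeros (the identity's log).
#' @export
zero_svf <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  velocity_field(array(0, dim = c(shape, 3)), spacing = spacing, origin = origin)
}

#' Smooth random velocity field with compact support
#'
#' White Gaussian noise per component, smoothed with a Gaussian kernel,
#' multiplied by a smooth boundary taper (a squared-sine ramp over
#' `taper_margin` voxels from every face, so the field vanishes at the
#' domain boundary — a flow on a bounded field of view must, or its
#' trajectories leave the grid), optionally multiplied by a user window,
#' and rescaled so the maximum voxel displacement norm equals `max_norm`.
#' Deterministic given `seed`.
#'
#' @param shape integer length-3 grid shape.
#' @param max_norm maximum per-voxel Euclidean norm, voxels.
#' @param smooth_sigma Gaussian smoothing, voxels (default `max(shape)/8`).
#' @param seed integer seed.
#' @param window optional 3D multiplier array in `[0,1]`.
#' @param taper_margin width of the boundary taper in voxels (default a
#'   quarter of the smallest axis); 0 disables it.
#' @param spacing,origin grid geometry.
#' @return A [velocity_field()].
#' @export
random_svf <- function(shape, max_norm = 1, smooth_sigma = NULL, seed = 1L,
                       window = NULL, taper_margin = NULL,
                       spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (is.null(smooth_sigma)) smooth_sigma <- max(shape) / 8
  if (is.null(taper_margin)) taper_margin <- round(min(shape) / 4)
  set.seed(seed)
  vec <- array(stats::rnorm(prod(shape) * 3), dim = c(shape, 3))
  vec <- gaussian_smooth_field(vec, smooth_sigma)
  if (taper_margin > 0) {
    tp <- boundary_taper(shape, taper_margin)
    for (c in 1:3) vec[, , , c] <- vec[, , , c] * tp
  }
  if (!is.null(window)) for (c in 1:3) vec[, , , c] <- vec[, , , c] * window
  mx <- max_vec_norm(vec)
  if (mx > 0) vec <- vec * (max_norm / mx)
  velocity_field(vec, spacing = spacing, origin = origin)
}

## Smooth [0,1] window: squared-sine ramp over `margin` voxels from each face.
boundary_taper <- function(shape, margin) {
  ramp <- function(n) {
    i <- seq_len(n)
    d <- pmin(i - 1, n - i)
    ifelse(d >= margin, 1, sin(pi / 2 * d / margin)^2)
  }
  w <- outer(outer(ramp(shape[1]), ramp(shape[2])), ramp(shape[3]))
  array(w, dim = shape)
}
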