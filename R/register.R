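#' Registration configuration
#'
#' Concrete instance of the diffeomorphic registration energy
#' `E(v) = Sim(moving o exp(v), fixed) + reg_weight * ||grad v||^2`,
#' minimized by multiresolution gradient descent with Gaussian-smoothed
#' updates and backtracking line search. Similarity is local normalized
#' cross-correlation (LNCC, default, box radius 2 voxels) or sum of squared
#' differences (SSD, sum convention); the regularizer is first-order
#' (diffusion), summed over voxels and components in voxel units.
#'
#' @param levels multiresolution pyramid depth (>= 1).
#' @param iters_per_level maximum gradient iterations per level (scalar or
#'   one value per level, coarse to fine).
#' @param similarity `"lncc"` or `"ssd"`.
#' @param lncc_radius LNCC box radius, voxels.
#' @param reg_weight nonnegative smoothness penalty weight.
#' @param step_size initial step length, voxels of maximum update.
#' @param smooth_update_sigma Gaussian smoothing of each velocity update,
#'   in level voxels (scalar, or one value per pyramid level, coarse to
#'   fine).
#' @param converge_tol relative energy change below which a level stops.
#' @param max_backtracks step halvings allowed per iteration before the
#'   level is declared converged.
#' @return A list of class `reg_config`.
#' @export
reg_config <- function(levels = 3L, iters_per_level = c(100L, 80L, 60L),
                       similarity = c("lncc", "ssd"), lncc_radius = 2L,
                       reg_weight = 0.15, step_size = 0.4,
                       smooth_update_sigma = 3, converge_tol = 1e-6,
                       max_backtracks = 10L) {
  similarity <- match.arg(similarity)
  if (levels < 1L) stop("reg_config: levels must be >= 1")
  if (reg_weight < 0) stop("reg_config: reg_weight must be nonnegative")
  if (step_size <= 0) stop("reg_config: step_size must be positive")
  if (length(iters_per_level) == 1L) iters_per_level <- rep(iters_per_level, levels)
  if (length(iters_per_level) != levels) stop("reg_config: iters_per_level length mismatch")
  if (length(smooth_update_sigma) == 1L) smooth_update_sigma <- rep(smooth_update_sigma, levels)
  if (length(smooth_update_sigma) != levels) stop("reg_config: smooth_update_sigma length mismatch")
  structure(list(levels = as.integer(levels), iters_per_level = as.integer(iters_per_level),
                 similarity = similarity, lncc_radius = as.integer(lncc_radius),
                 reg_weight = reg_weight, step_size = step_size,
                 smooth_update_sigma = smooth_update_sigma,
                 converge_tol = converge_tol, max_backtracks = as.integer(max_backtracks)),
            class = "reg_config")
}

## Uniform box mean filter with radius r (separable, replicate boundary),
## O(N) per axis via running sums.
box_mean3 <- function(vol, r) {
  if (r <= 0) return(vol)
  for (ax in 1:3) vol <- box_mean_axis(vol, r, ax)
  vol
}

box_mean_axis <- function(vol, r, ax) {
  d <- dim(vol)
  n <- d[ax]
  idx_pad <- c(rep(1L, r), seq_len(n), rep(n, r))
  padded <- switch(ax, vol[idx_pad, , , drop = FALSE],
                   vol[, idx_pad, , drop = FALSE], vol[, , idx_pad, drop = FALSE])
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  p <- aperm(padded, perm)
  dm <- dim(p)
  m <- matrix(p, nrow = dm[1])
  cs <- rbind(0, apply(m, 2, cumsum))
  w <- 2 * r + 1
  out <- (cs[(w + 1):(n + w), , drop = FALSE] - cs[1:n, , drop = FALSE]) / w
  dim(out) <- c(n, dm[2], dm[3])
  aperm(out, order(perm))
}

## Gaussian-like smoothing by two box passes (triangular kernel,
## sigma^2 = 2 (w^2 - 1) / 12). Two passes keep the filter's spectrum
## nonnegative (sinc^2), so smoothing a gradient yields a positive
## semidefinite preconditioner — the smoothed update stays a descent
## direction, which an odd number of box passes does not guarantee. Used in
## the registration inner loop where exact FIR smoothing at large sigma
## would dominate the runtime.
fast_smooth3 <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  r <- max(1L, round((sqrt(6 * sigma^2 + 1) - 1) / 2))
  for (pass in 1:2) vol <- box_mean3(vol, r)
  vol
}

fast_smooth_field <- function(vec4d, sigma) {
  for (c in 1:3) vec4d[, , , c] <- fast_smooth3(vec4d[, , , c], sigma)
  vec4d
}

lncc_terms <- function(fixed, warped, r, eps = 1e-6) {
  mF <- box_mean3(fixed, r); mW <- box_mean3(warped, r)
  cf <- fixed - mF; cw <- warped - mW
  A <- box_mean3(cf * cw, r)
  B <- box_mean3(cf * cf, r)
  C <- box_mean3(cw * cw, r)
  denom <- B * C
  cc <- ifelse(denom > eps, A^2 / denom, 0)
  list(cf = cf, cw = cw, A = A, B = B, C = C, denom = denom, cc = cc, eps = eps)
}

similarity_value <- function(fixed, warped, config) {
  if (config$similarity == "ssd") {
    sum((warped - fixed)^2)
  } else {
    lt <- lncc_terms(fixed, warped, config$lncc_radius)
    -sum(lt$cc)
  }
}

## dSim/dW (pointwise approximation for LNCC, exact for SSD).
similarity_force <- function(fixed, warped, config) {
  if (config$similarity == "ssd") {
    2 * (warped - fixed)
  } else {
    lt <- lncc_terms(fixed, warped, config$lncc_radius)
    ok <- lt$denom > lt$eps
    f <- array(0, dim = dim(fixed))
    f[ok] <- -2 * lt$A[ok] / lt$denom[ok] *
      (lt$cf[ok] - (lt$A[ok] / pmax(lt$C[ok], lt$eps)) * lt$cw[ok])
    f
  }
}

## First-order (diffusion) regularization penalty and its gradient.
reg_penalty <- function(vec4d) {
  s <- 0
  for (c in 1:3) {
    g <- gradient3(vec4d[, , , c])
    s <- s + sum(g$gx^2 + g$gy^2 + g$gz^2)
  }
  s
}

laplacian3 <- function(vol) {
  d <- dim(vol)
  out <- array(-6 * vol, dim = d)
  for (ax in 1:3) {
    n <- d[ax]
    ip <- pmin.int(seq_len(n) + 1L, n)
    im <- pmax.int(seq_len(n) - 1L, 1L)
    out <- out + switch(ax, vol[ip, , , drop = FALSE], vol[, ip, , drop = FALSE], vol[, , ip, drop = FALSE])
    out <- out + switch(ax, vol[im, , , drop = FALSE], vol[, im, , drop = FALSE], vol[, , im, drop = FALSE])
  }
  out
}

#' Registration energy
#'
#' Evaluates `Sim(moving o exp(v), fixed) + reg_weight * ||grad v||^2` for a
#' candidate velocity field. With `v = 0`, identical images and SSD
#' similarity the energy is 0.
#'
#' @param moving,fixed [image3d()]s on one grid.
#' @param v a [velocity_field()].
#' @param config a [reg_config()].
#' @return The scalar energy.
#' @export
energy <- function(moving, fixed, v, config = reg_config()) {
  check_same_grid(moving, fixed, "images")
  check_same_grid(moving, v, "image and velocity field")
  if (!all(is.finite(moving$values)) || !all(is.finite(fixed$values))) {
    stop("energy: non-finite image")
  }
  warped <- warp(moving, exp_svf(v))
  similarity_value(fixed$values, warped$values, config) +
    config$reg_weight * reg_penalty(v$vectors)
}

## Fast exponential used inside the descent loop: linear resampling with a
## coarser step policy — accuracy traded for speed, consistently for both
## the force computation and the line-search energies.
exp_fast <- function(v) exp_svf(v, max_step = 0.5, max_squarings = 10L, interp = "linear", second_order = FALSE)

energy_fast <- function(moving, fixed, v, config) {
  warped <- warp(moving, exp_fast(v))
  similarity_value(fixed$values, warped$values, config) +
    config$reg_weight * reg_penalty(v$vectors)
}

register_level <- function(mov, fix, vec, config, iters) {
  shape <- dim(mov)
  spacing <- c(1, 1, 1)
  img_m <- image3d(mov); img_f <- image3d(fix)
  v <- velocity_field(vec)
  E <- energy_fast(img_m, img_f, v, config)
  trace <- numeric(0)
  for (it in seq_len(iters)) {
    map <- exp_fast(v)
    W <- warp(img_m, map)$values
    f <- similarity_force(fix, W, config)
    gW <- gradient3(W)
    g <- array(0, dim = c(shape, 3))
    g[, , , 1] <- f * gW$gx
    g[, , , 2] <- f * gW$gy
    g[, , , 3] <- f * gW$gz
    if (config$reg_weight > 0) {
      for (c in 1:3) {
        g[, , , c] <- g[, , , c] - 2 * config$reg_weight * laplacian3(v$vectors[, , , c])
      }
    }
    g <- fast_smooth_field(g, config$smooth_update_sigma[1])
    gmax <- max_vec_norm(g)
    if (gmax == 0) break
    g <- g / gmax
    step <- config$step_size
    accepted <- FALSE
    for (bt in seq_len(config$max_backtracks + 1L)) {
      v_try <- velocity_field(v$vectors - step * g)
      E_try <- energy_fast(img_m, img_f, v_try, config)
      if (E_try < E - 1e-12 * abs(E)) {
        rel <- abs(E - E_try) / max(abs(E), 1e-12)
        v <- v_try
        E <- E_try
        accepted <- TRUE
        trace <- c(trace, E)
        if (rel < config$converge_tol) return(list(vec = v$vectors, trace = trace))
        break
      }
      step <- step / 2
    }
    if (!accepted) break
  }
  list(vec = v$vectors, trace = trace)
}

#' Pairwise diffeomorphic registration with a stationary velocity field
#'
#' Estimates the velocity field `v` minimizing the registration energy so
#' that `moving o exp(v)` matches `fixed`. Multiresolution gradient descent
#' from a zero (or supplied) initial field; each update is Gaussian-smoothed
#' and accepted only if the full energy decreases (backtracking line
#' search), so the accepted-step energy sequence is non-increasing within
#' each pyramid level.
#'
#' @param moving,fixed [image3d()]s on one grid (globally normalized
#'   intensities; see [normalize_global()]).
#' @param config a [reg_config()].
#' @param init optional initial [velocity_field()]; default zero.
#' @return A [velocity_field()] with attribute `"trace"`, a data.frame of
#'   per-level accepted energies.
#' @export
register <- function(moving, fixed, config = reg_config(), init = NULL) {
  check_same_grid(moving, fixed, "moving and fixed images")
  if (!all(is.finite(moving$values)) || !all(is.finite(fixed$values))) {
    stop("register: non-finite image")
  }
  shape <- grid_shape(moving)
  n_levels <- config$levels
  ## pyramid, coarse to fine; never coarser than 8 voxels per axis
  factors <- 2^((n_levels - 1):0)
  factors <- factors[min(shape) / factors >= 8 | factors == 1]
  mov_pyr <- lapply(factors, function(f) if (f == 1) moving$values else downsample_by(moving$values, f))
  fix_pyr <- lapply(factors, function(f) if (f == 1) fixed$values else downsample_by(fixed$values, f))
  iters <- config$iters_per_level
  if (length(iters) != length(factors)) {
    iters <- rep_len(iters, length(factors))
  }
  vec <- NULL
  traces <- list()
  for (l in seq_along(factors)) {
    shape_l <- dim(mov_pyr[[l]])
    if (is.null(vec)) {
      if (!is.null(init)) {
        check_same_grid(moving, init, "image and init field")
        vec <- resize_field(init$vectors, shape_l)
      } else {
        vec <- array(0, dim = c(shape_l, 3))
      }
    } else {
      vec <- resize_field(vec, shape_l)
    }
    ## update smoothing is specified in level voxels (its physical support
    ## grows at coarse levels, the usual demons convention); a vector gives
    ## explicit per-level control
    cfg_l <- config
    sig <- rep_len(config$smooth_update_sigma, length(factors))
    cfg_l$smooth_update_sigma <- sig[l]
    res <- register_level(mov_pyr[[l]], fix_pyr[[l]], vec, cfg_l, iters[l])
    vec <- res$vec
    traces[[l]] <- res$trace
  }
  out <- velocity_field(vec, spacing = moving$spacing, origin = moving$origin)
  tr <- do.call(rbind, lapply(seq_along(traces), function(l) {
    if (length(traces[[l]]) == 0) return(NULL)
    data.frame(level = l, iter = seq_along(traces[[l]]), energy = traces[[l]])
  }))
  attr(out, "trace") <- tr
  out
}

downsample_by <- function(vol, factor) {
  while (factor > 1) {
    vol <- downsample3(vol, 2L)
    factor <- factor / 2
  }
  vol
}

## Resize a [.,.,.,3] field to a new grid shape, scaling the vectors by the
## per-axis shape ratio (displacements are in voxel units of their own grid).
resize_field <- function(vec4d, out_shape) {
  in_shape <- dim(vec4d)[1:3]
  out <- array(0, dim = c(out_shape, 3))
  for (c in 1:3) {
    out[, , , c] <- resize3(vec4d[, , , c], out_shape) * (out_shape[c] / in_shape[c])
  }
  out
}
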