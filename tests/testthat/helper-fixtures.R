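## Shared fixtures and independent oracles for the test suite. Everything is
## generated in code; no binary fixtures.

## Constant velocity field (the taper-free analytic case).
const_svf <- function(shape, vec) {
  arr <- array(0, dim = c(shape, 3))
  for (c in 1:3) arr[, , , c] <- vec[c]
  velocity_field(arr)
}

## Independent endpoint oracle: explicit Euler integration of the flow of v
## at the given points (data.frame x, y, z), nstep steps of length 1/nstep.
## Samples the field with the same (cubic) spatial model the exponential
## assumes, so the two approximate the same continuous flow.
euler_flow <- function(v, pts, nstep = 1000) {
  vec <- v$vectors
  x <- pts$x; y <- pts$y; z <- pts$z
  ip <- function(c) svfatlas:::interp3(vec[, , , c], x, y, z, mode = "cubic", extrap = "clamp")
  for (s in seq_len(nstep)) {
    dx <- ip(1); dy <- ip(2); dz <- ip(3)
    x <- x + dx / nstep; y <- y + dy / nstep; z <- z + dz / nstep
  }
  cbind(x, y, z)
}

## Endpoints of a diffeo at integer voxel points.
diffeo_endpoints <- function(map, pts) {
  idx <- cbind(pts$x, pts$y, pts$z)
  cbind(pts$x + map$displacement[, , , 1][idx],
        pts$y + map$displacement[, , , 2][idx],
        pts$z + map$displacement[, , , 3][idx])
}

interior_points <- function(shape, margin = 3) {
  expand.grid(x = (1 + margin):(shape[1] - margin),
              y = (1 + margin):(shape[2] - margin),
              z = (1 + margin):(shape[3] - margin))
}

## Brute-force directed/symmetric Hausdorff oracle over full voxel sets.
brute_hausdorff <- function(A, B, percentile = 100) {
  dmat <- function(P, Q) {
    d <- matrix(0, nrow(P), nrow(Q))
    for (i in seq_len(nrow(P))) {
      d[i, ] <- sqrt((P[i, 1] - Q[, 1])^2 + (P[i, 2] - Q[, 2])^2 + (P[i, 3] - Q[, 3])^2)
    }
    d
  }
  dab <- apply(dmat(A, B), 1, min)
  dba <- apply(dmat(B, A), 1, min)
  q <- function(x) if (percentile >= 100) max(x) else as.numeric(stats::quantile(x, percentile / 100, type = 7))
  max(q(dab), q(dba))
}

## Sparse random voxel-set label map on a cubic grid (sets stay scattered so
## every voxel is its own surface).
random_voxel_set_map <- function(n_voxels, shape, label = 1L, seed = 1L) {
  set.seed(seed)
  arr <- array(0L, dim = shape)
  idx <- sample(prod(shape), n_voxels)
  arr[idx] <- label
  labelmap3d(arr)
}

mask_coords <- function(labmap, label) {
  which(labmap$labels == label, arr.ind = TRUE)
}

## Tiny labeled phantom for fusion/metric tests.
tiny_phantom <- function(grid = 16, age = 26, seed = 1L, noise_sd = 0.02) {
  p <- phantom_params(grid_shape = rep(grid, 3), noise_sd = noise_sd)
  make_phantom(age, p, seed = seed)
}
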