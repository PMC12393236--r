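#' 3D scalar image on a regular grid
#'
#' A scalar volume with voxel spacing (mm) and world origin (mm). Intensities
#' are arbitrary units; atlas construction expects globally normalized images
#' (see [normalize_global()]).
#'
#' @param values numeric 3D array of intensities.
#' @param spacing numeric length-3, per-axis voxel size in mm (strictly positive).
#' @param origin numeric length-3, world position of voxel (1,1,1) in mm.
#' @return An object of class `image3d` with fields `values`, `spacing`, `origin`.
#' @export
image3d <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("image3d: `values` must be a 3D array")
  if (any(dim(values) == 0L)) stop("image3d: empty grid")
  if (!all(is.finite(values))) stop("image3d: non-finite intensities")
  if (length(spacing) != 3L || any(spacing <= 0)) stop("image3d: spacing must be 3 positive values")
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image3d")
}

#' Integer-coded 3D label map
#'
#' @param labels integer 3D array; 0 is background by convention.
#' @param spacing,origin grid geometry, as in [image3d()].
#' @param key optional named character vector mapping label id to name.
#' @return An object of class `labelmap3d`.
#' @export
labelmap3d <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0), key = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("labelmap3d: `labels` must be a 3D array")
  if (!all(is.finite(labels))) stop("labelmap3d: non-finite labels")
  if (any(labels != round(labels))) stop("labelmap3d: labels must be integer-coded")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), key = key),
            class = "labelmap3d")
}

#' Stationary velocity field
#'
#' The Lie-algebra representation of a diffeomorphism: a time-constant vector
#' field, in voxel units, on the same grid as the images it acts on. The zero
#' field represents the identity map.
#'
#' @param vectors numeric 4D array `[nx, ny, nz, 3]`, voxel units.
#' @param spacing,origin grid geometry shared with associated images.
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(vectors, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  vectors <- as.array(vectors)
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L) stop("velocity_field: `vectors` must be [nx,ny,nz,3]")
  if (any(d[1:3] == 0L)) stop("velocity_field: empty grid")
  if (!all(is.finite(vectors))) stop("velocity_field: non-finite field")
  structure(list(vectors = vectors, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "velocity_field")
}

#' Dense diffeomorphic map
#'
#' A dense per-voxel displacement (voxel units). Maps produced by [exp_svf()]
#' keep their generating velocity field in `$svf`, so that taking the log of
#' such a map is bookkeeping, never a numerical estimation. Maps entering a
#' Log-Euclidean mean must carry an SVF.
#'
#' @param displacement numeric 4D array `[nx, ny, nz, 3]`, voxel units.
#' @param spacing,origin grid geometry.
#' @param svf optional generating [velocity_field()].
#' @return An object of class `diffeo`.
#' @export
diffeo <- function(displacement, spacing = c(1, 1, 1), origin = c(0, 0, 0), svf = NULL) {
  displacement <- as.array(displacement)
  d <- dim(displacement)
  if (length(d) != 4L || d[4] != 3L) stop("diffeo: `displacement` must be [nx,ny,nz,3]")
  if (!all(is.finite(displacement))) stop("diffeo: non-finite displacement")
  if (!is.null(svf) && !inherits(svf, "velocity_field")) stop("diffeo: `svf` must be a velocity_field")
  structure(list(displacement = displacement, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), svf = svf),
            class = "diffeo")
}

grid_shape <- function(x) {
  if (inherits(x, "image3d")) dim(x$values)
  else if (inherits(x, "labelmap3d")) dim(x$labels)
  else if (inherits(x, "velocity_field")) dim(x$vectors)[1:3]
  else if (inherits(x, "diffeo")) dim(x$displacement)[1:3]
  else stop("unknown grid object")
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(grid_shape(a), grid_shape(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

check_same_grid <- function(a, b, what = "operands") {
  if (!same_grid(a, b)) stop("incompatible grids: ", what, " must share shape, spacing and origin")
  invisible(TRUE)
}

#' @export
print.image3d <- function(x, ...) {
  cat("image3d ", paste(dim(x$values), collapse = "x"),
      " spacing [", paste(signif(x$spacing, 4), collapse = ", "),
      "] range [", signif(min(x$values), 4), ", ", signif(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.labelmap3d <- function(x, ...) {
  cat("labelmap3d ", paste(dim(x$labels), collapse = "x"),
      " labels {", paste(sort(unique(as.vector(x$labels))), collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' @export
print.velocity_field <- function(x, ...) {
  cat("velocity_field ", paste(dim(x$vectors)[1:3], collapse = "x"),
      " max|v| ", signif(max_vec_norm(x$vectors), 4), " voxels\n", sep = "")
  invisible(x)
}

#' @export
print.diffeo <- function(x, ...) {
  cat("diffeo ", paste(dim(x$displacement)[1:3], collapse = "x"),
      " max|d| ", signif(max_vec_norm(x$displacement), 4), " voxels",
      if (!is.null(x$svf)) " (carries SVF)" else "", "\n", sep = "")
  invisible(x)
}

max_vec_norm <- function(vec4d) {
  sqrt(max(vec4d[, , , 1]^2 + vec4d[, , , 2]^2 + vec4d[, , , 3]^2))
}

## ---- low-level grid numerics -------------------------------------------

## Trilinear / nearest / cubic (Catmull-Rom) interpolation of a 3D array at
## continuous voxel coordinates (1-based). extrap = "fill": outside samples
## take `fill`; extrap = "clamp": coordinates clamped to the domain
## (constant extension). Cubic always clamps.
interp3 <- function(vol, ci, cj, ck, mode = c("linear", "nearest", "cubic"),
                    extrap = c("fill", "clamp"), fill = 0) {
  mode <- match.arg(mode)
  extrap <- match.arg(extrap)
  d <- dim(vol)
  n <- length(ci)
  if (mode == "cubic") {
    ci <- pmin(pmax(ci, 1), d[1]); cj <- pmin(pmax(cj, 1), d[2]); ck <- pmin(pmax(ck, 1), d[3])
    i0 <- floor(ci); j0 <- floor(cj); k0 <- floor(ck)
    fi <- ci - i0; fj <- cj - j0; fk <- ck - k0
    crw <- function(f) list(0.5 * (-f^3 + 2 * f^2 - f), 0.5 * (3 * f^3 - 5 * f^2 + 2),
                            0.5 * (-3 * f^3 + 4 * f^2 + f), 0.5 * (f^3 - f^2))
    wx <- crw(fi); wy <- crw(fj); wz <- crw(fk)
    out <- numeric(n)
    for (a in 0:3) {
      ia <- pmin.int(pmax.int(i0 + a - 1, 1), d[1])
      for (b in 0:3) {
        jb <- pmin.int(pmax.int(j0 + b - 1, 1), d[2])
        wab <- wx[[a + 1]] * wy[[b + 1]]
        for (cc in 0:3) {
          kc <- pmin.int(pmax.int(k0 + cc - 1, 1), d[3])
          out <- out + wab * wz[[cc + 1]] * vol[(ia - 1) + d[1] * ((jb - 1) + d[2] * (kc - 1)) + 1]
        }
      }
    }
    return(out)
  }
  if (mode == "nearest") {
    i <- round(ci); j <- round(cj); k <- round(ck)
    if (extrap == "clamp") {
      i <- pmin.int(pmax.int(i, 1), d[1])
      j <- pmin.int(pmax.int(j, 1), d[2])
      k <- pmin.int(pmax.int(k, 1), d[3])
      return(vol[(i - 1) + d[1] * ((j - 1) + d[2] * (k - 1)) + 1])
    }
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    out <- rep.int(fill, n)
    out[ok] <- vol[(i[ok] - 1) + d[1] * ((j[ok] - 1) + d[2] * (k[ok] - 1)) + 1]
    return(out)
  }
  if (extrap == "clamp") {
    ci <- pmin(pmax(ci, 1), d[1])
    cj <- pmin(pmax(cj, 1), d[2])
    ck <- pmin(pmax(ck, 1), d[3])
  }
  i0 <- floor(ci); j0 <- floor(cj); k0 <- floor(ck)
  ## keep the upper face inside the cell below it
  i0 <- pmin(i0, d[1] - 1); j0 <- pmin(j0, d[2] - 1); k0 <- pmin(k0, d[3] - 1)
  i0 <- pmax(i0, if (extrap == "clamp") 1 else -Inf)
  j0 <- pmax(j0, if (extrap == "clamp") 1 else -Inf)
  k0 <- pmax(k0, if (extrap == "clamp") 1 else -Inf)
  fi <- ci - i0; fj <- cj - j0; fk <- ck - k0
  out <- numeric(n)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) fi else 1 - fi) * (if (dj) fj else 1 - fj) * (if (dk) fk else 1 - fk)
    ii <- i0 + di; jj <- j0 + dj; kk <- k0 + dk
    if (extrap == "clamp") {
      v <- vol[(ii - 1) + d[1] * ((jj - 1) + d[2] * (kk - 1)) + 1]
    } else {
      ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
      v <- rep.int(fill, n)
      v[ok] <- vol[(ii[ok] - 1) + d[1] * ((jj[ok] - 1) + d[2] * (kk[ok] - 1)) + 1]
    }
    out <- out + w * v
  }
  out
}

## Voxel-index coordinate arrays for a grid shape (1-based).
grid_coords <- function(shape) {
  list(x = array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), dim = shape),
       y = array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]), dim = shape),
       z = array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), dim = shape))
}

## Sample a 4D vector field at displaced coordinates; returns 4D array.
sample_field <- function(vec4d, ci, cj, ck, extrap = "clamp", mode = "linear") {
  d <- dim(vec4d)
  res <- array(0, dim = d)
  for (c in 1:3) {
    res[, , , c] <- interp3(vec4d[, , , c], ci, cj, ck, mode = mode, extrap = extrap)
  }
  res
}

## Separable Gaussian smoothing of a 3D array (sigma in voxels, truncated at
## 3 sigma, replicate boundary handling). sigma = 0 returns the input.
gaussian_smooth3 <- function(vol, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3)
  d <- dim(vol)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    k <- k / sum(k)
    acc <- array(0, dim = d)
    n <- d[ax]
    for (t in (-r):r) {
      idx <- pmin.int(pmax.int(seq_len(n) + t, 1L), n)
      shifted <- switch(ax,
                        vol[idx, , , drop = FALSE],
                        vol[, idx, , drop = FALSE],
                        vol[, , idx, drop = FALSE])
      acc <- acc + k[t + r + 1] * shifted
    }
    vol <- acc
  }
  vol
}

gaussian_smooth_field <- function(vec4d, sigma) {
  for (c in 1:3) vec4d[, , , c] <- gaussian_smooth3(vec4d[, , , c], sigma)
  vec4d
}

## Central-difference gradient of a 3D array, one-sided at boundaries.
## Returns list(gx, gy, gz); divide by spacing if physical units are wanted.
gradient3 <- function(vol, spacing = c(1, 1, 1)) {
  d <- dim(vol)
  g <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax]
    ip <- pmin.int(seq_len(n) + 1L, n)
    im <- pmax.int(seq_len(n) - 1L, 1L)
    denom <- (ip - im)  # 2 interior, 1 at the faces
    fwd <- switch(ax, vol[ip, , , drop = FALSE], vol[, ip, , drop = FALSE], vol[, , ip, drop = FALSE])
    bwd <- switch(ax, vol[im, , , drop = FALSE], vol[, im, , drop = FALSE], vol[, , im, drop = FALSE])
    den <- switch(ax,
                  array(denom, dim = d),
                  array(rep(denom, each = d[1]), dim = d),
                  array(rep(denom, each = d[1] * d[2]), dim = d))
    g[[ax]] <- (fwd - bwd) / (den * spacing[ax])
  }
  names(g) <- c("gx", "gy", "gz")
  g
}

## Block-mean downsampling of a 3D array by an integer factor per axis.
downsample3 <- function(vol, factor = 2L) {
  d <- dim(vol)
  nd <- ceiling(d / factor)
  ## pad by edge replication to a multiple of factor
  padded <- vol[pmin.int(seq_len(nd[1] * factor), d[1]),
                pmin.int(seq_len(nd[2] * factor), d[2]),
                pmin.int(seq_len(nd[3] * factor), d[3]), drop = FALSE]
  dim(padded) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  out <- apply(padded, c(2, 4, 6), mean)
  array(out, dim = nd)
}

## Separable linear resize of a 3D array to a target shape (half-pixel
## convention; rows of each axis matrix sum to 1, so constants are preserved).
resize3 <- function(vol, out_shape) {
  d <- dim(vol)
  for (ax in 1:3) {
    if (d[ax] == out_shape[ax]) next
    M <- resize_matrix(d[ax], out_shape[ax])
    vol <- ttm3(vol, M, ax)
    d <- dim(vol)
  }
  vol
}

resize_matrix <- function(n_in, n_out) {
  s <- (seq_len(n_out) - 0.5) * (n_in / n_out) + 0.5
  s <- pmin(pmax(s, 1), n_in)
  i0 <- pmin(floor(s), n_in - if (n_in > 1) 1 else 0)
  i0 <- pmax(i0, 1)
  f <- s - i0
  M <- matrix(0, n_out, n_in)
  M[cbind(seq_len(n_out), i0)] <- 1 - f
  M[cbind(seq_len(n_out), pmin(i0 + 1, n_in))] <-
    M[cbind(seq_len(n_out), pmin(i0 + 1, n_in))] + f
  M
}

## Tensor-times-matrix along axis `ax` of a 3D array.
ttm3 <- function(vol, M, ax) {
  d <- dim(vol)
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  v <- aperm(vol, perm)
  dm <- dim(v)
  v <- M %*% matrix(v, nrow = dm[1])
  dim(v) <- c(nrow(M), dm[2], dm[3])
  aperm(v, order(perm))
}
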