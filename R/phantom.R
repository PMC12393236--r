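#' Parameters of the age-parameterized brain phantom
#'
#' The phantom emulates the anatomy the atlas models: an ellipsoidal "brain"
#' whose radius grows linearly with gestational age, a surface ribbon
#' ("cortex") perturbed by sinusoidal folding whose amplitude increases with
#' age (folding is zero at 21 weeks, mimicking gyrification onset), and an
#' inner ellipsoid ("ventricles"). Geometric defaults scale with the grid so
#' the same cohort model can be generated at any resolution.
#'
#' @param grid_shape integer length-3 voxel counts (default 32^3).
#' @param base_radius brain radius at 21 weeks, voxels.
#' @param growth_rate radius growth, voxels/week.
#' @param folding_rate folding amplitude growth, voxels/week (amplitude is
#'   `folding_rate * (age - 21)`, zero at 21 weeks).
#' @param folding_freq angular frequency of the folding pattern, cycles/radian.
#' @param axes_ratio per-axis ellipsoid semi-axis ratios.
#' @param ventricle_scale inner-ellipsoid scale relative to the brain radius.
#' @param cortex_thickness ribbon thickness as a fraction of the radius
#'   (floored at 1.5 voxels).
#' @param tissue_means named intensities for background, white matter,
#'   cortex, ventricles.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param age_range supported gestational-age range, weeks.
#' @return A list of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(32, 32, 32),
                           base_radius = 0.28 * min(grid_shape),
                           growth_rate = 0.011 * min(grid_shape),
                           folding_rate = 0.006 * min(grid_shape),
                           folding_freq = 5,
                           axes_ratio = c(1, 0.88, 0.8),
                           ventricle_scale = 0.35,
                           cortex_thickness = 0.14,
                           tissue_means = c(bg = 0, wm = 0.55, cortex = 0.85, vent = 0.25),
                           noise_sd = 0.02,
                           age_range = c(21, 37)) {
  stopifnot(base_radius > 0, growth_rate >= 0, length(grid_shape) == 3)
  structure(list(grid_shape = as.integer(grid_shape), base_radius = base_radius,
                 growth_rate = growth_rate, folding_rate = folding_rate,
                 folding_freq = folding_freq, axes_ratio = axes_ratio,
                 ventricle_scale = ventricle_scale, cortex_thickness = cortex_thickness,
                 tissue_means = tissue_means, noise_sd = noise_sd,
                 age_range = age_range),
            class = "phantom_params")
}

#' A subject: image plus gestational age
#'
#' @param id subject identifier.
#' @param image an [image3d()].
#' @param age gestational age, weeks.
#' @return An object of class `subject`.
#' @export
subject <- function(id, image, age) {
  if (!inherits(image, "image3d")) stop("subject: `image` must be an image3d")
  structure(list(id = as.character(id), image = image, age = as.numeric(age)),
            class = "subject")
}

#' @export
print.subject <- function(x, ...) {
  cat("subject ", x$id, " (", x$age, " weeks) ",
      paste(dim(x$image$values), collapse = "x"), "\n", sep = "")
  invisible(x)
}

## Deterministic phantom geometry (no noise): returns label array and the
## normalized radial coordinate used to build it.
phantom_geometry <- function(age, params) {
  shape <- params$grid_shape
  r <- params$base_radius + params$growth_rate * (age - params$age_range[1])
  amp <- params$folding_rate * (age - params$age_range[1])
  ctr <- (shape + 1) / 2
  g <- grid_coords(shape)
  ax <- r * params$axes_ratio
  ux <- (g$x - ctr[1]) / ax[1]
  uy <- (g$y - ctr[2]) / ax[2]
  uz <- (g$z - ctr[3]) / ax[3]
  rho <- sqrt(ux^2 + uy^2 + uz^2)
  theta <- atan2(uy, ux)
  phi <- acos(ifelse(rho > 0, uz / pmax(rho, 1e-12), 1))
  pert <- (amp / r) * sin(params$folding_freq * theta) * sin(phi) * sin(3 * phi)
  boundary <- 1 + pert
  thick <- max(params$cortex_thickness, 1.5 / r)
  labels <- array(0L, dim = shape)
  labels[rho <= boundary] <- 1L                      # white matter / interior
  labels[rho <= boundary & rho > boundary - thick] <- 2L  # cortex ribbon
  labels[rho <= params$ventricle_scale] <- 3L        # ventricles
  list(labels = labels, rho = rho, radius = r)
}

#' Generate a brain-like phantom at a given age
#'
#' Returns a noisy multi-tissue image and its ground-truth label map
#' (0 background, 1 white matter, 2 cortex, 3 ventricles). Bit-reproducible
#' for a fixed `(params, seed)`.
#'
#' @param age gestational age, weeks; must lie in `params$age_range`.
#' @param params a [phantom_params()].
#' @param seed integer seed for the additive noise.
#' @return List with `subject` (a [subject()]) and `labels` (a [labelmap3d()]).
#' @export
make_phantom <- function(age, params = phantom_params(), seed = 1L) {
  if (age < params$age_range[1] || age > params$age_range[2]) {
    stop("make_phantom: age ", age, " outside supported range [",
         params$age_range[1], ", ", params$age_range[2], "]")
  }
  geo <- phantom_geometry(age, params)
  means <- params$tissue_means
  img <- array(means[["bg"]], dim = params$grid_shape)
  img[geo$labels == 1L] <- means[["wm"]]
  img[geo$labels == 2L] <- means[["cortex"]]
  img[geo$labels == 3L] <- means[["vent"]]
  if (params$noise_sd > 0) {
    set.seed(seed)
    img <- img + array(stats::rnorm(length(img), sd = params$noise_sd),
                       dim = dim(img))
  }
  list(subject = subject(sprintf("phantom_age%.1f_seed%d", age, seed),
                         image3d(img), age),
       labels = labelmap3d(geo$labels))
}

## Smooth spatial window covering the head and a margin, in [0,1];
## confines synthetic deformations to regions with intensity support.
head_window <- function(age, params, margin = 1.25) {
  geo <- phantom_geometry(age, params)
  w <- array(as.numeric(geo$rho <= margin), dim = params$grid_shape)
  w <- gaussian_smooth3(w, sigma = max(params$grid_shape) / 16)
  w / max(w)
}

#' Generate a pair of phantoms related by a known smooth warp
#'
#' The second image is the first (noise-free) phantom resampled through
#' `exp(u)` for a smooth random velocity field `u` with maximum displacement
#' `warp_scale` voxels, confined to the head region by a smooth window;
#' independent noise is then added to each image. `u` is returned as
#' registration ground truth.
#'
#' @inheritParams make_phantom
#' @param warp_scale maximum displacement of the ground-truth warp, voxels.
#' @return List with subjects `a`, `b`, label maps `labels_a`, `labels_b`,
#'   the ground-truth [velocity_field()] `svf`, and the smooth window.
#' @export
make_warped_pair <- function(age, params = phantom_params(), warp_scale = 2,
                             seed = 1L) {
  clean_params <- params; clean_params$noise_sd <- 0
  base <- make_phantom(age, clean_params, seed = seed)
  win <- head_window(age, params)
  u <- random_svf(params$grid_shape, max_norm = warp_scale,
                  smooth_sigma = max(params$grid_shape) / 6,
                  seed = seed + 1000L, window = win)
  if (warp_scale > 0) {
    map <- exp_svf(u)
    img_b <- warp(base$subject$image, map)
    lab_b <- warp(base$labels, map)
  } else {
    img_b <- base$subject$image
    lab_b <- base$labels
  }
  set.seed(seed + 2000L)
  va <- base$subject$image$values
  vb <- img_b$values
  if (params$noise_sd > 0) {
    va <- va + array(stats::rnorm(length(va), sd = params$noise_sd), dim = dim(va))
    vb <- vb + array(stats::rnorm(length(vb), sd = params$noise_sd), dim = dim(vb))
  }
  list(a = subject("pair_a", image3d(va), age),
       b = subject("pair_b", image3d(vb), age),
       labels_a = base$labels, labels_b = lab_b,
       svf = u, window = win)
}

#' Generate a synthetic cohort with anatomical jitter
#'
#' Draws per-subject ages (uniformly over `age_range`, or from a supplied
#' age histogram), then perturbs each phantom by a small random smooth warp
#' and a global intensity scale — the cohort-level variability the atlas has
#' to average out.
#'
#' @param n number of subjects.
#' @param age_range length-2 numeric, weeks; defaults to `params$age_range`.
#' @param params a [phantom_params()].
#' @param seed integer seed.
#' @param ages optional explicit age vector (overrides sampling).
#' @param age_hist optional named numeric vector of bin weights (names are
#'   bin-center ages); ages are drawn multinomially from the bins.
#' @param jitter_scale maximum displacement of the per-subject jitter warp,
#'   voxels (default 4% of the smallest grid axis).
#' @param intensity_sd standard deviation of the per-subject intensity scale
#'   about 1.
#' @return List of per-subject lists with `subject` and `labels`.
#' @export
make_cohort <- function(n, age_range = NULL, params = phantom_params(), seed = 1L,
                        ages = NULL, age_hist = NULL,
                        jitter_scale = 0.04 * min(params$grid_shape),
                        intensity_sd = 0.03) {
  if (n == 0L) return(list())
  if (is.null(age_range)) age_range <- params$age_range
  set.seed(seed)
  if (is.null(ages)) {
    if (!is.null(age_hist)) {
      centers <- as.numeric(names(age_hist))
      ages <- sample(centers, n, replace = TRUE, prob = age_hist / sum(age_hist))
    } else {
      ages <- stats::runif(n, age_range[1], age_range[2])
    }
  }
  if (length(ages) != n) stop("make_cohort: `ages` must have length n")
  scales <- stats::rnorm(n, mean = 1, sd = intensity_sd)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    clean_params <- params; clean_params$noise_sd <- 0
    base <- make_phantom(ages[i], clean_params, seed = seed)
    win <- head_window(ages[i], params)
    jit <- random_svf(params$grid_shape, max_norm = jitter_scale,
                      smooth_sigma = max(params$grid_shape) / 5,
                      seed = seed * 10000L + i, window = win)
    map <- exp_svf(jit)
    img <- warp(base$subject$image, map)
    lab <- warp(base$labels, map)
    set.seed(seed * 10000L + i + 5000L)
    v <- img$values * scales[i]
    if (params$noise_sd > 0) {
      v <- v + array(stats::rnorm(length(v), sd = params$noise_sd), dim = dim(v))
    }
    out[[i]] <- list(subject = subject(sprintf("sub%03d", i), image3d(v), ages[i]),
                     labels = lab, jitter = jit)
  }
  out
}

#' Simulate raters with known confusion matrices
#'
#' Each rater's voxel label is drawn independently from its confusion-matrix
#' row conditioned on the true label — the generative model under which
#' STAPLE's rater parameters are identifiable, used as a parameter-recovery
#' fixture.
#'
#' @param truth a [labelmap3d()].
#' @param confusions list of row-stochastic L x L matrices, with rows/columns
#'   ordered by the sorted label set of `truth` (rows: true label; columns:
#'   observed label).
#' @param seed integer seed.
#' @return List of [labelmap3d()]s, one per rater.
#' @export
simulate_raters <- function(truth, confusions, seed = 1L) {
  labs <- sort(unique(as.vector(truth$labels)))
  L <- length(labs)
  for (th in confusions) {
    if (!is.matrix(th) || any(dim(th) != L)) {
      stop("simulate_raters: each confusion matrix must be ", L, "x", L)
    }
    if (any(abs(rowSums(th) - 1) > 1e-10) || any(th < 0) || any(th > 1)) {
      stop("simulate_raters: confusion rows must be probabilities summing to 1")
    }
  }
  set.seed(seed)
  tl <- match(as.vector(truth$labels), labs)
  out <- vector("list", length(confusions))
  for (j in seq_along(confusions)) {
    obs <- integer(length(tl))
    for (l in seq_len(L)) {
      idx <- which(tl == l)
      if (length(idx)) {
        obs[idx] <- sample(labs, length(idx), replace = TRUE,
                           prob = confusions[[j]][l, ])
      }
    }
    arr <- array(obs, dim = dim(truth$labels))
    out[[j]] <- labelmap3d(arr, spacing = truth$spacing, origin = truth$origin,
                           key = truth$key)
  }
  out
}
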