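#' Global intensity normalization
#'
#' Linearly rescales intensities so the robust range (1st-99th percentile)
#' maps to `[0, 1]`. With a `reference` image, instead matches median and
#' interquartile range to the reference. Atlas construction assumes its
#' input images have passed through this map.
#'
#' @param image an [image3d()].
#' @param reference optional [image3d()] whose median/IQR to match.
#' @return A normalized [image3d()].
#' @export
normalize_global <- function(image, reference = NULL) {
  v <- image$values
  if (max(v) == min(v)) stop("normalize_global: degenerate (constant) image")
  if (is.null(reference)) {
    q <- stats::quantile(v, c(0.01, 0.99), type = 7)
    if (q[2] == q[1]) stop("normalize_global: degenerate robust range")
    out <- (v - q[1]) / (q[2] - q[1])
  } else {
    m <- stats::median(v); i <- stats::IQR(v)
    mr <- stats::median(reference$values); ir <- stats::IQR(reference$values)
    if (i == 0) stop("normalize_global: degenerate IQR")
    out <- (v - m) / i * ir + mr
  }
  image3d(out, spacing = image$spacing, origin = image$origin)
}

#' Weighted template from warped subject images
#'
#' Voxelwise kernel-weighted average of the subjects pulled back into atlas
#' space: `sum_i w_i(t) * warp(I_i, Tinv_i)`. Only subjects in the weights'
#' support contribute; `transforms` entries may be `NULL` for the identity.
#'
#' @param subjects list of [subject()]s.
#' @param transforms list of [diffeo()] pullback maps (the inverse total
#'   transforms), aligned with `subjects`; `NULL` entries mean identity.
#' @param weights a `kernel_weights` object aligned with `subjects`.
#' @return An [image3d()] template.
#' @export
build_template <- function(subjects, transforms, weights) {
  n <- length(subjects)
  if (length(weights$weights) != n) stop("build_template: weights/subject mismatch")
  if (!is.null(transforms) && length(transforms) != n) {
    stop("build_template: transforms/subject mismatch")
  }
  ref <- subjects[[weights$support[1]]]$image
  acc <- array(0, dim = grid_shape(ref))
  for (i in weights$support) {
    img <- subjects[[i]]$image
    if (!is.null(transforms) && !is.null(transforms[[i]])) {
      img <- warp(img, transforms[[i]])
    }
    acc <- acc + weights$weights[i] * img$values
  }
  image3d(acc, spacing = ref$spacing, origin = ref$origin)
}

age_key <- function(t) sprintf("%.4f", t)

## Fold a sequence of SVF logs into log(phibar_k o ... o phibar_1) by BCH.
fold_bch <- function(svfs, order = 2L) {
  acc <- svfs[[1]]
  if (length(svfs) > 1L) {
    for (s in 2:length(svfs)) acc <- compose_bch(svfs[[s]], acc, order = order)
  }
  acc
}

#' Longitudinal coordinate maps from the residual-mean history
#'
#' Builds `psi_{k,i}(t)`, the map relating the atlas space at the subject's
#' observed age `t_i` to any other age `t`, as the composition
#' `[prod_s phibar_s(t)] o [prod_s phibar_s(t_i)]^{-1}` of the per-iteration
#' residual Log-Euclidean means — realized entirely on the stored velocity
#' fields through BCH composition, so the result stays inside the
#' stationary-velocity model. An empty history yields the identity at every
#' age.
#'
#' @param history list over iterations; each element a named list (by
#'   [age_key()]d age) of [velocity_field()]s, the logs of the residual
#'   means at that age.
#' @param subject_age observed age `t_i`, weeks.
#' @param target_ages ages at which to evaluate the map.
#' @param order BCH truncation order.
#' @return Named list of [diffeo()]s (each carrying its SVF), keyed by age.
#' @export
update_longitudinal_maps <- function(history, subject_age, target_ages, order = 2L) {
  out <- list()
  if (length(history) == 0L) {
    return(stats::setNames(vector("list", length(target_ages)), age_key(target_ages)))
  }
  get_seq <- function(t) {
    key <- age_key(t)
    lapply(history, function(h) {
      if (is.null(h[[key]])) stop("update_longitudinal_maps: missing residual SVF at age ", t)
      h[[key]]
    })
  }
  A_ti <- fold_bch(get_seq(subject_age), order = order)
  for (t in target_ages) {
    A_t <- if (abs(t - subject_age) < 1e-12) A_ti else fold_bch(get_seq(t), order = order)
    log_psi <- compose_bch(A_t, invert_svf(A_ti), order = order)
    out[[age_key(t)]] <- exp_svf(log_psi)
  }
  out
}

#' Residual atlas deformation at an age
#'
#' The Log-Euclidean mean of the age-adjusted atlas-to-subject maps:
#' `exp(-sum_i w_i log phi_i(t))`, the correction that re-centers the atlas
#' (removes drift toward particular subjects).
#'
#' @param age_specific list of [velocity_field()]s, the logs of the
#'   age-specific deformations of the supported subjects.
#' @param weights numeric weights over those subjects (nonnegative, sum 1).
#' @return A [diffeo()] carrying its SVF.
#' @export
residual_deformation <- function(age_specific, weights) {
  log_euclidean_mean_inverse(age_specific, weights)
}

#' An atlas timepoint
#'
#' @param t age, weeks.
#' @param template the template [image3d()].
#' @param residual the residual [diffeo()] (carrying its SVF).
#' @param iteration iteration index that produced it.
#' @param weights the `kernel_weights` used.
#' @return An object of class `atlas_timepoint`.
#' @export
atlas_timepoint <- function(t, template, residual, iteration, weights = NULL) {
  if (!is.null(residual) && is.null(residual$svf)) {
    stop("atlas_timepoint: residual must carry its SVF")
  }
  structure(list(t = t, template = template, residual = residual,
                 iteration = iteration, weights = weights),
            class = "atlas_timepoint")
}

#' @export
print.atlas_timepoint <- function(x, ...) {
  cat("atlas_timepoint t = ", x$t, " weeks (iteration ", x$iteration, ")\n", sep = "")
  invisible(x)
}

#' Iterative spatiotemporal atlas construction
#'
#' Alternates, for `n_iter` iterations: kernel-weighted template generation
#' at the observed ages; registration of every subject to the template at
#' its own age (zero-initialized stationary-velocity registration);
#' composition of the longitudinal coordinate maps `psi` and the
#' age-specific deformations `phi_i(t)` across the supported ages (via BCH
#' on the stored velocity fields); and the residual Log-Euclidean mean
#' `phibar_k(t) = exp(-sum_i w_i log phi_i(t))` that re-centers the atlas.
#' Total transforms are `T_i(t) = phibar(t) o psi_i(t) o phi_i`. Templates
#' can then be emitted at arbitrary continuous target ages.
#'
#' Per-iteration diagnostics record, per age, the drift norm
#' `||sum_i w_i log phi_i(t)||` — the mean voxel displacement norm of the
#' weighted log mean, zero for a perfectly centered atlas — evaluated over
#' a fixed per-age anatomy mask (`drift`; velocity noise in the empty
#' background is not atlas bias) and over the whole grid (`drift_all`),
#' plus the mean absolute difference between warped subjects and template.
#'
#' @param cohort list of per-subject lists with at least `$subject` (a
#'   [subject()]); a plain list of [subject()]s is also accepted.
#' @param target_ages ages (weeks) at which to emit atlas timepoints.
#' @param n_iter number of outer iterations (default 4).
#' @param config a [reg_config()].
#' @param kernel list of kernel options passed to [compute_weights()]
#'   (`sigma`, `truncation`, `sigma_min`, `sigma_max`, `n_eff_min`).
#' @param normalize apply [normalize_global()] to each input image.
#' @param order BCH truncation order for all map compositions.
#' @param verbose print per-iteration progress.
#' @return An object of class `sta_atlas`: list with `timepoints` (one
#'   [atlas_timepoint()] per target age), `transforms` (per subject: id,
#'   age, `log_phi`, and named lists `log_total` / `psi` over target ages),
#'   `diagnostics` (data.frame: iteration, age, drift, mean_abs_diff), and
#'   `subjects` (the normalized inputs).
#' @export
build_atlas <- function(cohort, target_ages, n_iter = 4L, config = reg_config(),
                        kernel = list(), normalize = TRUE, order = 2L,
                        verbose = FALSE) {
  subjects <- lapply(cohort, function(x) if (inherits(x, "subject")) x else x$subject)
  n <- length(subjects)
  if (n == 0L) stop("build_atlas: empty cohort")
  if (normalize) {
    for (i in seq_len(n)) subjects[[i]]$image <- normalize_global(subjects[[i]]$image)
  }
  subj_ages <- vapply(subjects, function(s) s$age, numeric(1))
  observed <- sort(unique(subj_ages))
  all_ages <- sort(unique(c(observed, target_ages)))
  kw <- function(t) do.call(compute_weights, c(list(ages = subj_ages, t = t), kernel))
  weights_at <- stats::setNames(lapply(all_ages, kw), age_key(all_ages))

  ## fixed per-age anatomy masks (kernel-weighted mean image, identity
  ## transforms): the drift diagnostic is evaluated over anatomy — velocity
  ## noise in empty background is not atlas bias — and the mask must not
  ## change across iterations or the ratio would be incomparable
  fg_mask_at <- stats::setNames(lapply(all_ages, function(t) {
    w <- weights_at[[age_key(t)]]
    build_template(subjects, NULL, w)$values > 0.15
  }), age_key(all_ages))

  active <- rep(TRUE, n)                   # subjects not failed by registration
  hist_phibar <- list()                    # per iteration: age -> velocity_field
  log_total <- vector("list", n)           # per subject: age -> velocity_field
  log_phi <- vector("list", n)
  psi_maps <- vector("list", n)
  diagnostics <- NULL
  ref <- subjects[[1]]$image

  for (k in seq_len(n_iter)) {
    ## -- templates at observed ages from the previous total transforms
    templates <- list()
    for (t in observed) {
      w <- reweight(weights_at[[age_key(t)]], active)
      trans <- lapply(seq_len(n), function(i) {
        if (k == 1L || is.null(log_total[[i]])) return(NULL)
        lt <- log_total[[i]][[age_key(t)]]
        if (is.null(lt)) NULL else exp_svf(invert_svf(lt))
      })
      templates[[age_key(t)]] <- build_template(subjects, trans, w)
    }

    ## -- register every subject to the template at its own age
    v_hat <- vector("list", n)
    sim_at <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      if (!active[i]) next
      tmpl <- templates[[age_key(subj_ages[i])]]
      v_hat[[i]] <- tryCatch(
        register(subjects[[i]]$image, tmpl, config = config),
        error = function(e) {
          warning("registration failed for subject ", subjects[[i]]$id, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(v_hat[[i]])) {
        active[i] <- FALSE
        w_left <- sum(abs(subj_ages[active] - subj_ages[i]) <= 1)
        if (w_left < 2) stop("build_atlas: fewer than 2 subjects remain at age ",
                             subj_ages[i], "; aborting")
        next
      }
      wimg <- warp(subjects[[i]]$image, exp_svf(v_hat[[i]]))
      sim_at[i] <- mean(abs(wimg$values - tmpl$values))
    }

    ## -- longitudinal maps and age-specific deformations; residual means
    phibar_k <- list()
    log_phi_age <- list()  # age -> list over supported subjects
    for (i in seq_len(n)) {
      if (!active[i]) next
      log_phi[[i]] <- invert_svf(v_hat[[i]])   # log phi_i = -v_hat (subject -> atlas)
    }
    drift_rows <- NULL
    for (t in all_ages) {
      w <- reweight(weights_at[[age_key(t)]], active)
      sup <- w$support
      logs <- vector("list", length(sup))
      for (s in seq_along(sup)) {
        i <- sup[s]
        psi_i <- update_longitudinal_maps(hist_phibar, subj_ages[i], t, order = order)
        lp <- psi_i[[age_key(t)]]
        logs[[s]] <- if (is.null(lp)) log_phi[[i]] else {
          compose_bch(lp$svf, log_phi[[i]], order = order)
        }
      }
      D <- Reduce(`+`, lapply(seq_along(sup), function(s) w$weights[sup[s]] * logs[[s]]$vectors))
      dnorm_vox <- sqrt(D[, , , 1]^2 + D[, , , 2]^2 + D[, , , 3]^2)
      fg <- fg_mask_at[[age_key(t)]]
      phibar_k[[age_key(t)]] <- velocity_field(-D, spacing = ref$spacing, origin = ref$origin)
      log_phi_age[[age_key(t)]] <- stats::setNames(logs, as.character(sup))
      drift_rows <- rbind(drift_rows,
                          data.frame(iteration = k, age = t,
                                     drift = mean(dnorm_vox[fg]),
                                     drift_all = mean(dnorm_vox),
                                     mean_abs_diff = mean(sim_at[sup], na.rm = TRUE)))
    }
    hist_phibar[[k]] <- phibar_k
    diagnostics <- rbind(diagnostics, drift_rows)

    ## -- total transforms T_i(t) = phibar(t) o phi_i(t)
    for (i in seq_len(n)) {
      if (!active[i]) { log_total[[i]] <- NULL; next }
      lt <- list()
      for (t in all_ages) {
        sup <- weights_at[[age_key(t)]]$support
        key <- age_key(t)
        if (!(i %in% sup)) next
        lphi <- log_phi_age[[key]][[as.character(i)]]
        lt[[key]] <- compose_bch(phibar_k[[key]], lphi, order = order)
      }
      ## ages outside this subject's support still need a transform for
      ## template building at its own age: always present by construction
      log_total[[i]] <- lt
    }
    if (verbose) {
      message(sprintf("iteration %d: mean drift %.4f", k,
                      mean(drift_rows$drift)))
    }
  }

  ## -- emit atlas timepoints at the target ages
  timepoints <- list()
  for (t in target_ages) {
    key <- age_key(t)
    w <- reweight(weights_at[[key]], active)
    trans <- lapply(seq_len(n), function(i) {
      if (!active[i] || is.null(log_total[[i]][[key]])) NULL
      else exp_svf(invert_svf(log_total[[i]][[key]]))
    })
    tmpl <- build_template(subjects, trans, w)
    residual <- exp_svf(hist_phibar[[n_iter]][[key]])
    timepoints[[key]] <- atlas_timepoint(t, tmpl, residual, n_iter, w)
  }

  transforms <- lapply(seq_len(n), function(i) {
    if (!active[i]) return(NULL)
    list(id = subjects[[i]]$id, age = subj_ages[i],
         log_phi = log_phi[[i]], log_total = log_total[[i]])
  })
  structure(list(timepoints = timepoints, transforms = transforms,
                 diagnostics = diagnostics, subjects = subjects,
                 target_ages = target_ages, n_iter = n_iter),
            class = "sta_atlas")
}

## Re-normalize kernel weights after dropping failed subjects.
reweight <- function(w, active) {
  if (all(active)) return(w)
  ww <- w$weights
  ww[!active] <- 0
  if (sum(ww) == 0) stop("no active subjects remain in the support of t = ", w$t)
  ww <- ww / sum(ww)
  structure(list(weights = ww, t = w$t, sigma = w$sigma, support = which(ww > 0)),
            class = "kernel_weights")
}

#' @export
print.sta_atlas <- function(x, ...) {
  cat("sta_atlas: ", length(x$timepoints), " timepoint(s) at ages ",
      paste(x$target_ages, collapse = ", "), " weeks; ",
      x$n_iter, " iteration(s)\n", sep = "")
  invisible(x)
}

#' Label the atlas by weighted majority vote
#'
#' Propagates each contributing subject's ground-truth labels into atlas
#' space through the same pullback transforms used for the intensities, and
#' takes the kernel-weighted majority label per voxel.
#'
#' @param atlas an `sta_atlas` from [build_atlas()].
#' @param cohort the cohort list used to build it (each element with
#'   `$labels`, a [labelmap3d()]).
#' @param t target age (must be one of the atlas target ages).
#' @return A [labelmap3d()] in atlas space.
#' @export
atlas_label_map <- function(atlas, cohort, t) {
  key <- age_key(t)
  tp <- atlas$timepoints[[key]]
  if (is.null(tp)) stop("atlas_label_map: no timepoint at age ", t)
  w <- tp$weights
  labs_all <- sort(unique(unlist(lapply(cohort, function(x) unique(as.vector(x$labels$labels))))))
  shape <- grid_shape(tp$template)
  score <- array(0, dim = c(shape, length(labs_all)))
  for (i in w$support) {
    tr <- atlas$transforms[[i]]
    if (is.null(tr) || is.null(tr$log_total[[key]])) next
    warped <- warp(cohort[[i]]$labels, exp_svf(invert_svf(tr$log_total[[key]])))
    for (l in seq_along(labs_all)) {
      score[, , , l] <- score[, , , l] + w$weights[i] * (warped$labels == labs_all[l])
    }
  }
  flat <- matrix(score, ncol = length(labs_all))
  win <- max.col(flat, ties.method = "first")
  labelmap3d(array(labs_all[win], dim = shape),
             spacing = tp$template$spacing, origin = tp$template$origin)
}
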