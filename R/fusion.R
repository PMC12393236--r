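#' Propagate atlas labels through a deformation
#'
#' Nearest-neighbor resampling of an integer label map through a
#' diffeomorphic map (background fill 0) — step 2 of multi-atlas
#' segmentation.
#'
#' @param atlas_labels a [labelmap3d()].
#' @param map a [diffeo()] on the same grid.
#' @return A [labelmap3d()].
#' @export
propagate <- function(atlas_labels, map) {
  warp(atlas_labels, map, mode = "nearest", fill = 0)
}

#' Probabilistic STAPLE label fusion
#'
#' Expectation-maximization over a consensus segmentation and per-rater
#' confusion matrices. E-step: voxel posterior over true labels
#' proportional to `prior(l) * prod_j theta_j(l, d_j)`; M-step:
#' `theta_j(l, m) = sum_n posterior_n(l) 1[d_jn = m] / sum_n posterior_n(l)`.
#' Class priors are re-estimated in the M-step by default (mean posterior
#' per label): the pooled rater frequencies that seed them systematically
#' overweight rare labels (off-diagonal noise from abundant classes leaks
#' into them), which would bias every confusion row. Iterates until the
#' largest confusion-matrix change falls below `tol` or `max_iter` is
#' reached. The observed-data log-likelihood is non-decreasing across
#' iterations (returned for inspection). Consensus is the voxelwise
#' posterior argmax, ties broken by the smallest label id.
#'
#' @param maps list of at least two [labelmap3d()]s on one grid.
#' @param prior initial class prior: `"empirical"` (default; label
#'   frequencies pooled over raters), `"uniform"`, or a numeric vector over
#'   the label set.
#' @param prior_update re-estimate the class prior each M-step (default
#'   TRUE); set FALSE to keep the initial prior fixed.
#' @param tol convergence tolerance on `max |delta theta|` (default 1e-5).
#' @param max_iter maximum EM iterations (default 50).
#' @param theta_init initial diagonal confusion value (default 0.9;
#'   off-diagonal mass spread uniformly).
#' @param theta_prior_count strength (in pseudo-voxels) of a weak Dirichlet
#'   prior centered on the initial confusion matrix, added to the M-step
#'   counts. This pins confusion rows of labels that carry (almost) no
#'   posterior mass — otherwise unidentifiable and prone to label-swapped
#'   degenerate solutions — and is negligible against any real voxel count.
#' @return An object of class `staple_fit`: list with `consensus`
#'   (a [labelmap3d()]), `theta` (list of confusion matrices, truth in rows,
#'   labels as dimnames), `posterior` (voxels x labels matrix), `labels`
#'   (the label set), `loglik` (per-iteration trace), `iterations`.
#' @export
staple_fuse <- function(maps, prior = "empirical", tol = 1e-5, max_iter = 50L,
                        theta_init = 0.9, theta_prior_count = 1,
                        prior_update = TRUE) {
  if (length(maps) < 2L) stop("staple_fuse: need at least 2 label maps")
  ref <- maps[[1]]
  for (m in maps[-1]) check_same_grid(ref, m, "label maps")
  labs <- sort(unique(unlist(lapply(maps, function(m) unique(as.vector(m$labels))))))
  L <- length(labs)
  if (L < 2L) {
    ## degenerate: unanimous single label
    cons <- labelmap3d(array(labs, dim = grid_shape(ref)),
                       spacing = ref$spacing, origin = ref$origin)
    return(structure(list(consensus = cons,
                          theta = replicate(length(maps), matrix(1, 1, 1,
                            dimnames = list(labs, labs)), simplify = FALSE),
                          posterior = matrix(1, prod(grid_shape(ref)), 1),
                          labels = labs, loglik = 0, iterations = 0L),
                     class = "staple_fit"))
  }
  J <- length(maps)
  N <- prod(grid_shape(ref))
  D <- matrix(0L, N, J)
  for (j in seq_len(J)) D[, j] <- match(as.vector(maps[[j]]$labels), labs)

  if (identical(prior, "uniform")) {
    pr <- rep(1 / L, L)
  } else if (identical(prior, "empirical")) {
    pr <- tabulate(as.vector(D), nbins = L)
    pr <- pr / sum(pr)
  } else {
    if (length(prior) != L) stop("staple_fuse: prior must have one entry per label (", L, ")")
    pr <- prior / sum(prior)
  }

  theta <- replicate(J, {
    th <- matrix((1 - theta_init) / (L - 1), L, L, dimnames = list(labs, labs))
    diag(th) <- theta_init
    th
  }, simplify = FALSE)

  estep <- function() {
    logW <- matrix(log(pr), N, L, byrow = TRUE)
    for (j in seq_len(J)) {
      lt <- log(pmax(theta[[j]], 1e-300))
      logW <- logW + t(lt)[D[, j], , drop = FALSE]   # row d_jn, over truth l: theta[l, d]
    }
    mx <- logW[, 1]
    for (l in seq_len(L)[-1]) mx <- pmax(mx, logW[, l])
    Wn <- exp(logW - mx)
    rs <- rowSums(Wn)
    list(W = Wn / rs, loglik = sum(mx + log(rs)))
  }

  loglik <- numeric(0)
  W <- NULL
  for (it in seq_len(max_iter)) {
    es <- estep()
    W <- es$W
    loglik <- c(loglik, es$loglik)
    ## M-step
    if (prior_update) pr <- colMeans(W)
    theta_new <- theta
    delta <- 0
    theta0 <- matrix((1 - theta_init) / (L - 1), L, L)
    diag(theta0) <- theta_init
    for (j in seq_len(J)) {
      th <- matrix(0, L, L, dimnames = list(labs, labs))
      for (m in seq_len(L)) {
        idx <- D[, j] == m
        if (any(idx)) th[, m] <- colSums(W[idx, , drop = FALSE])
      }
      th <- th + theta_prior_count * theta0
      th <- th / rowSums(th)
      delta <- max(delta, max(abs(th - theta[[j]])))
      theta_new[[j]] <- th
    }
    theta <- theta_new
    if (delta < tol) break
  }
  ## final E-step so posterior matches the returned theta
  es <- estep()
  W <- es$W
  loglik <- c(loglik, es$loglik)
  cons_idx <- max.col(W, ties.method = "first")   # smallest label id on ties
  cons <- labelmap3d(array(labs[cons_idx], dim = grid_shape(ref)),
                     spacing = ref$spacing, origin = ref$origin, key = ref$key)
  structure(list(consensus = cons, theta = theta, posterior = W, labels = labs,
                 loglik = loglik, iterations = it),
            class = "staple_fit")
}

#' @export
print.staple_fit <- function(x, ...) {
  cat("staple_fit: ", length(x$theta), " raters, ", length(x$labels),
      " labels, ", x$iterations, " EM iteration(s), final loglik ",
      signif(x$loglik[length(x$loglik)], 6), "\n", sep = "")
  invisible(x)
}

#' Multi-atlas segmentation of a query subject
#'
#' Three steps: (1) select atlas timepoints within `window` weeks of the
#' query's gestational age (the age-matching rule for atlas-based fetal
#' segmentation); (2) register each selected template to the query and
#' propagate its labels through the estimated deformation; (3) fuse the
#' propagated maps with probabilistic STAPLE (a single selected atlas is
#' returned directly).
#'
#' @param query a [subject()] (image plus age).
#' @param atlas_bank list of entries, each a list with `timepoint` (an
#'   [atlas_timepoint()]) and `labels` (a [labelmap3d()] in that template's
#'   space).
#' @param config a [reg_config()].
#' @param window age window half-width in weeks (default 1).
#' @param normalize normalize the query and templates before registration.
#' @param ... passed to [staple_fuse()].
#' @return An object of class `mas_result`: list with `labels` (the fused
#'   [labelmap3d()]), `per_atlas` (propagated label maps), `ages` (selected
#'   atlas ages), and `staple` (the `staple_fit`, or `NULL` for a single
#'   atlas).
#' @export
mas_segment <- function(query, atlas_bank, config = reg_config(), window = 1,
                        normalize = TRUE, ...) {
  ages <- vapply(atlas_bank, function(e) e$timepoint$t, numeric(1))
  keep <- which(abs(ages - query$age) <= window)
  if (length(keep) == 0L) {
    stop("no atlas within ", window, " week(s) of query age ", query$age,
         " (bank ages: ", paste(ages, collapse = ", "), ")")
  }
  qimg <- if (normalize) normalize_global(query$image) else query$image
  per_atlas <- vector("list", length(keep))
  for (s in seq_along(keep)) {
    e <- atlas_bank[[keep[s]]]
    tmpl <- if (normalize) normalize_global(e$timepoint$template) else e$timepoint$template
    v <- register(tmpl, qimg, config = config)
    per_atlas[[s]] <- propagate(e$labels, exp_svf(v))
  }
  if (length(per_atlas) == 1L) {
    return(structure(list(labels = per_atlas[[1]], per_atlas = per_atlas,
                          ages = ages[keep], staple = NULL),
                     class = "mas_result"))
  }
  fit <- staple_fuse(per_atlas, ...)
  structure(list(labels = fit$consensus, per_atlas = per_atlas,
                 ages = ages[keep], staple = fit),
            class = "mas_result")
}

#' @export
print.mas_result <- function(x, ...) {
  cat("mas_result: fused ", length(x$per_atlas), " atlas(es) at ages ",
      paste(signif(x$ages, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}
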