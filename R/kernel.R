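#' Gaussian kernel-regression weights on gestational age
#'
#' Computes normalized Gaussian weights centered at a target age `t`:
#' `g_i(t) = (sigma_t * sqrt(2*pi))^-1 * exp(-(t_i - t)^2 / (2 sigma_t^2))`.
#' Weights of subjects farther than the truncation width (default one week)
#' from `t` are set exactly to zero, and the remaining weights renormalized
#' to sum to 1 on the realized support.
#'
#' @param ages numeric vector of subject ages (weeks).
#' @param t target age (weeks).
#' @param sigma bandwidth in weeks; `NULL` (default) adapts it with
#'   [adapt_sigma()].
#' @param truncation truncation width in weeks (default 1).
#' @param sigma_min,sigma_max,n_eff_min passed to [adapt_sigma()] when
#'   `sigma` is `NULL`.
#' @return An object of class `kernel_weights`: list with `weights` (length
#'   of `ages`, summing to 1), `t`, `sigma`, and `support` (indices with
#'   nonzero weight).
#' @export
compute_weights <- function(ages, t, sigma = NULL, truncation = 1,
                            sigma_min = 0.25, sigma_max = 1, n_eff_min = 5) {
  if (length(ages) == 0L) stop("compute_weights: empty age list")
  inside <- abs(ages - t) <= truncation
  if (!any(inside)) {
    stop("no subjects within ", truncation, " week(s) of target age t = ", t)
  }
  if (is.null(sigma)) {
    sigma <- adapt_sigma(ages, t, sigma_min = sigma_min, sigma_max = sigma_max,
                         n_eff_min = n_eff_min, truncation = truncation)
  }
  if (sigma <= 0) stop("compute_weights: sigma must be positive")
  g <- stats::dnorm(ages, mean = t, sd = sigma)
  g[!inside] <- 0
  w <- g / sum(g)
  structure(list(weights = w, t = t, sigma = sigma, support = which(w > 0)),
            class = "kernel_weights")
}

#' Adaptive kernel bandwidth from effective sample size
#'
#' Returns the smallest bandwidth `sigma >= sigma_min` at which the effective
#' sample size `(sum g)^2 / sum g^2` of the Gaussian weights, over subjects
#' inside the truncation window, reaches `n_eff_min`; capped at `sigma_max`.
#' This guarantees a minimum effective cohort behind every template while
#' keeping the kernel as age-specific as the data allow.
#'
#' @inheritParams compute_weights
#' @param n_eff_min minimum effective sample size (default 5).
#' @param grid_step resolution of the bandwidth scan in weeks.
#' @return Bandwidth in weeks.
#' @export
adapt_sigma <- function(ages, t, sigma_min = 0.25, sigma_max = 1, n_eff_min = 5,
                        truncation = 1, grid_step = 0.005) {
  if (length(ages) == 0L) stop("adapt_sigma: empty age list")
  d <- ages[abs(ages - t) <= truncation] - t
  if (length(d) == 0L) return(sigma_max)
  ess <- function(s) {
    g <- exp(-d^2 / (2 * s^2))
    sum(g)^2 / sum(g^2)
  }
  if (ess(sigma_min) >= n_eff_min) return(sigma_min)
  for (s in seq(sigma_min, sigma_max, by = grid_step)) {
    if (ess(s) >= n_eff_min) return(s)
  }
  sigma_max
}

#' @export
print.kernel_weights <- function(x, ...) {
  cat("kernel_weights at t = ", x$t, " weeks (sigma = ", signif(x$sigma, 4),
      "): ", length(x$support), " of ", length(x$weights),
      " subjects in support\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.kernel_weights <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(index = seq_along(x$weights), weight = x$weights,
             t = x$t, sigma = x$sigma)
}
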