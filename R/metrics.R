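#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` for the voxel sets carrying `label` in each map.
#' When both sets are empty the overlap is perfect by convention and 1 is
#' returned with a message.
#'
#' @param a,b [labelmap3d()]s on the same grid.
#' @param label the label id to compare.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b, label) {
  check_same_grid(a, b, "label maps")
  ma <- a$labels == label
  mb <- b$labels == label
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0L) {
    message("dice: label ", label, " absent from both maps; returning 1")
    return(1)
  }
  2 * sum(ma & mb) / (na + nb)
}

## Surface voxels of a binary mask: mask voxels with at least one
## 6-neighbor outside the mask (grid faces count as outside).
surface_voxels <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, dim = d)
  for (ax in 1:3) {
    n <- d[ax]
    ip <- pmin.int(seq_len(n) + 1L, n)
    im <- pmax.int(seq_len(n) - 1L, 1L)
    fwd <- switch(ax, mask[ip, , , drop = FALSE], mask[, ip, , drop = FALSE], mask[, , ip, drop = FALSE])
    bwd <- switch(ax, mask[im, , , drop = FALSE], mask[, im, , drop = FALSE], mask[, , im, drop = FALSE])
    interior <- interior & fwd & bwd
    ## face voxels border the outside
    if (ax == 1) { interior[1, , ] <- FALSE; interior[n, , ] <- FALSE }
    if (ax == 2) { interior[, 1, ] <- FALSE; interior[, n, ] <- FALSE }
    if (ax == 3) { interior[, , 1] <- FALSE; interior[, , n] <- FALSE }
  }
  which(mask & !interior, arr.ind = TRUE)
}

## Directed distances: for each row of A (n x 3), min Euclidean distance to
## the rows of B, computed in chunks to bound memory.
directed_min_dists <- function(A, B, chunk = 2048L) {
  nB <- nrow(B)
  b_sq <- rowSums(B^2)
  out <- numeric(nrow(A))
  for (s in seq(1, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(A))
    Ac <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ac^2), b_sq, "+") - 2 * Ac %*% t(B)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Hausdorff distance between two label masks
#'
#' Symmetrized (by max) directed surface-to-surface distance for the voxel
#' sets carrying `label`; `percentile` 100 gives the classical Hausdorff
#' distance, 95 the robust variant. Distances are Euclidean in voxel units
#' by default, or mm when `units = "mm"` (coordinates scaled by spacing).
#'
#' @inheritParams dice
#' @param percentile 100 (default) or 95.
#' @param units `"voxel"` or `"mm"`.
#' @return Distance (voxels or mm).
#' @export
hausdorff <- function(a, b, label, percentile = 100, units = c("voxel", "mm")) {
  check_same_grid(a, b, "label maps")
  units <- match.arg(units)
  ma <- a$labels == label
  mb <- b$labels == label
  if (!any(ma) || !any(mb)) {
    stop("hausdorff: undefined metric — label ", label, " empty in ",
         if (!any(ma)) "first" else "second", " map")
  }
  sa <- surface_voxels(ma)
  sb <- surface_voxels(mb)
  if (units == "mm") {
    sa <- sweep(sa, 2, a$spacing, "*")
    sb <- sweep(sb, 2, a$spacing, "*")
  }
  dab <- directed_min_dists(sa, sb)
  dba <- directed_min_dists(sb, sa)
  q <- function(x) if (percentile >= 100) max(x) else as.numeric(stats::quantile(x, percentile / 100, type = 7))
  max(q(dab), q(dba))
}

#' Median edge sharpness of an image
#'
#' Atlas-quality metric: the median gradient magnitude over detected edge
#' voxels. Edges are detected by thresholding the gradient magnitude at a
#' percentile (default 90th) of the nonzero gradients inside the foreground
#' mask; the gradient is computed by central differences scaled by voxel
#' spacing. Residual blur in an average template lowers this score, so a
#' sharper (better-aligned) atlas scores higher.
#'
#' @param image an [image3d()].
#' @param edge_percentile percentile of nonzero foreground gradient
#'   magnitudes defining the edge threshold.
#' @param fg_mask optional logical 3D array; default: voxels above 5% of the
#'   99th-percentile intensity.
#' @param detector optional function(image3d) returning a logical 3D edge
#'   mask, replacing the percentile rule.
#' @return Median gradient magnitude over edge voxels.
#' @export
edge_sharpness <- function(image, edge_percentile = 90, fg_mask = NULL,
                           detector = NULL) {
  v <- image$values
  if (max(v) == min(v)) stop("edge_sharpness: constant image has no edges")
  g <- gradient3(v, spacing = image$spacing)
  gm <- sqrt(g$gx^2 + g$gy^2 + g$gz^2)
  if (!is.null(detector)) {
    edges <- detector(image)
  } else {
    if (is.null(fg_mask)) {
      fg_mask <- v > 0.05 * stats::quantile(v, 0.99, type = 7)
    }
    cand <- gm[fg_mask & gm > 0]
    if (length(cand) == 0L) stop("edge_sharpness: no edges detected in the foreground")
    thr <- stats::quantile(cand, edge_percentile / 100, type = 7)
    edges <- fg_mask & gm >= thr
  }
  if (!any(edges)) stop("edge_sharpness: no edges detected")
  stats::median(gm[edges])
}

#' Per-label segmentation report
#'
#' Dice and Hausdorff distance per label (nonzero labels present in either
#' map), with a mean/sd summary row. Labels empty in one of the maps get an
#' `NA` Hausdorff distance with a note.
#'
#' @param pred,truth [labelmap3d()]s on one grid.
#' @param percentile Hausdorff percentile (100 or 95).
#' @param units `"voxel"` or `"mm"`.
#' @return An object of class `metric_report`: list with `per_label`
#'   (data.frame: label, dice, hd) and `summary` (data.frame of mean/sd).
#' @export
report <- function(pred, truth, percentile = 100, units = "voxel") {
  check_same_grid(pred, truth, "label maps")
  labs <- sort(union(unique(as.vector(pred$labels)), unique(as.vector(truth$labels))))
  labs <- labs[labs != 0]
  rows <- lapply(labs, function(l) {
    d <- dice(pred, truth, l)
    h <- tryCatch(hausdorff(pred, truth, l, percentile = percentile, units = units),
                  error = function(e) {
                    message("report: hd undefined for label ", l, " (", conditionMessage(e), ")")
                    NA_real_
                  })
    data.frame(label = l, dice = d, hd = h)
  })
  per_label <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("dice", "hd"),
    mean = c(mean(per_label$dice), mean(per_label$hd, na.rm = TRUE)),
    sd = c(stats::sd(per_label$dice), stats::sd(per_label$hd, na.rm = TRUE)))
  structure(list(per_label = per_label, summary = summ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("metric_report:\n")
  print(x$per_label, row.names = FALSE)
  cat("summary:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a metric report to CSV
#'
#' @param x a `metric_report`.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_report_csv <- function(x, path) {
  utils::write.csv(x$per_label, path, row.names = FALSE)
  invisible(path)
}
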