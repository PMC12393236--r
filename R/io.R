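#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file (.nii / .nii.gz), preserving voxel spacing and the
#' world origin from the stored transform. 3D volumes become [image3d()] or
#' [labelmap3d()]; 4D volumes with 3 components on the last axis become
#' [velocity_field()]s (the serialization convention for velocity and
#' displacement fields, voxel units).
#'
#' @param path file path.
#' @param label read as an integer label map.
#' @return An [image3d()], [labelmap3d()] or [velocity_field()].
#' @export
load_volume <- function(path, label = FALSE) {
  if (!file.exists(path)) stop("load_volume: cannot read ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim = dim(arr))  # drop NIfTI attributes
  nd <- length(dim(arr))
  sp <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  if (nd == 4L) {
    if (dim(arr)[4] != 3L) stop("load_volume: 4D volume must have 3 vector components")
    return(velocity_field(arr, spacing = sp, origin = org))
  }
  if (nd != 3L) stop("load_volume: expected a 3D volume (or 4D vector field), got ", nd, "D")
  if (label) labelmap3d(arr, spacing = sp, origin = org)
  else image3d(arr, spacing = sp, origin = org)
}

#' Write a volume, label map or vector field as NIfTI
#'
#' Label maps are stored as 32-bit integers; velocity fields and
#' displacement fields as 4D floats with the vector component on the last
#' axis (voxel-unit convention).
#'
#' @param obj an [image3d()], [labelmap3d()], [velocity_field()] or
#'   [diffeo()] (a diffeo writes its displacement).
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
save_volume <- function(obj, path) {
  if (inherits(obj, "image3d")) {
    arr <- obj$values; dt <- "double"
  } else if (inherits(obj, "labelmap3d")) {
    arr <- obj$labels; dt <- "int32"
  } else if (inherits(obj, "velocity_field")) {
    arr <- obj$vectors; dt <- "double"
  } else if (inherits(obj, "diffeo")) {
    arr <- obj$displacement; dt <- "double"
  } else stop("save_volume: unsupported object of class ", class(obj)[1])
  im <- RNifti::asNifti(arr)
  RNifti::pixdim(im) <- obj$spacing
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(obj$spacing)
  aff[1:3, 4] <- obj$origin
  RNifti::sform(im) <- structure(aff, code = 2L)
  RNifti::qform(im) <- structure(aff, code = 2L)
  RNifti::writeNifti(im, path, datatype = dt)
  invisible(path)
}

#' Read a cohort table
#'
#' CSV with columns `subject_id`, `age_weeks`, `image_path` and optionally
#' `label_path`; paths are resolved relative to the CSV's directory.
#'
#' @param path CSV path.
#' @return Cohort list (elements with `$subject` and optionally `$labels`).
#' @export
load_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age_weeks", "image_path")
  if (!all(need %in% names(tab))) {
    stop("load_cohort_csv: columns must include ", paste(need, collapse = ", "))
  }
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  lapply(seq_len(nrow(tab)), function(i) {
    img <- load_volume(resolve(tab$image_path[i]))
    out <- list(subject = subject(tab$subject_id[i], img, tab$age_weeks[i]))
    if ("label_path" %in% names(tab) && nzchar(tab$label_path[i])) {
      out$labels <- load_volume(resolve(tab$label_path[i]), label = TRUE)
    }
    out
  })
}

#' Write a cohort to disk
#'
#' Writes each subject image (and label map, when present) as NIfTI and a
#' `cohort.csv` index.
#'
#' @param cohort cohort list (elements with `$subject`, optional `$labels`).
#' @param dir output directory (created if needed).
#' @return Path of the written CSV, invisibly.
#' @export
save_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(e) {
    s <- e$subject
    imgf <- paste0(s$id, ".nii.gz")
    save_volume(s$image, file.path(dir, imgf))
    labf <- ""
    if (!is.null(e$labels)) {
      labf <- paste0(s$id, "_labels.nii.gz")
      save_volume(e$labels, file.path(dir, labf))
    }
    data.frame(subject_id = s$id, age_weeks = s$age, image_path = imgf,
               label_path = labf)
  })
  csv <- file.path(dir, "cohort.csv")
  utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE)
  invisible(csv)
}

#' Read / write a label-key file
#'
#' One `id name` pair per line (the released-atlas label-key text layout).
#'
#' @param path file path.
#' @return Named character vector (names are the ids).
#' @export
read_label_key <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ids <- sub("^\\s*(\\S+)\\s+.*$", "\\1", lines)
  nms <- sub("^\\s*\\S+\\s+(.*)$", "\\1", lines)
  stats::setNames(nms, ids)
}

#' @rdname read_label_key
#' @param key named character vector (names are ids).
#' @export
write_label_key <- function(key, path) {
  writeLines(paste(names(key), key), path)
  invisible(path)
}

#' Export kernel weights as CSV
#'
#' @param w a `kernel_weights` object.
#' @param ages the subject ages the weights refer to.
#' @param path output CSV.
#' @param ids optional subject ids.
#' @return `path`, invisibly.
#' @export
write_weights_csv <- function(w, ages, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("sub%03d", seq_along(ages))
  utils::write.csv(data.frame(subject_id = ids, age = ages, weight = w$weights),
                   path, row.names = FALSE)
  invisible(path)
}

#' Load a registration configuration from YAML
#'
#' Keys mirror the arguments of [reg_config()].
#'
#' @param path YAML path.
#' @return A [reg_config()].
#' @export
load_reg_config <- function(path) {
  conf <- yaml::read_yaml(path)
  do.call(reg_config, conf)
}
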