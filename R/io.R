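#' Write an image series to NIfTI with sidecars
#'
#' One 4-D NIfTI file plus the scheme sidecar in the conventional text
#' dialects: `.bval`/`.bvec` (space-separated, bvec as 3 rows x N columns)
#' for diffusion series, a JSON echo-time list for multi-echo series, and
#' the masks as separate NIfTI volumes.
#'
#' @param series an [image_series].
#' @param path output path without extension.
#' @return invisibly, the paths written.
#' @export
write_series <- function(series, path) {
  pix <- c(series$voxel_dims, 1)
  img <- RNifti::asNifti(series$data, pixdim = c(pix))
  paths <- c(nii = paste0(path, ".nii"))
  RNifti::writeNifti(img, paths[["nii"]], compression = 0)
  sch <- series$scheme
  if (inherits(sch, "bvalue_scheme")) {
    paths[["bval"]] <- paste0(path, ".bval")
    writeLines(paste(format(sch$b, trim = TRUE), collapse = " "),
               paths[["bval"]])
  } else if (inherits(sch, "gradient_scheme")) {
    paths[["bval"]] <- paste0(path, ".bval")
    paths[["bvec"]] <- paste0(path, ".bvec")
    bv <- c(sch$b_low, rep(sch$b_high, nrow(sch$directions)))
    writeLines(paste(format(bv, trim = TRUE), collapse = " "),
               paths[["bval"]])
    G <- rbind(0, sch$directions)           # b=0 column is zero
    writeLines(apply(t(G), 1, function(r)
      paste(format(r, digits = 8, trim = TRUE), collapse = " ")),
      paths[["bvec"]])
  } else if (inherits(sch, "echo_scheme")) {
    paths[["tes"]] <- paste0(path, "_tes.json")
    jsonlite::write_json(list(echo_times_ms = sch$te), paths[["tes"]],
                         digits = NA)
  }
  if (!is.null(series$liver_mask)) {
    paths[["mask"]] <- paste0(path, "_mask.nii")
    RNifti::writeNifti(RNifti::asNifti(series$liver_mask + 0),
                       paths[["mask"]], compression = 0)
  }
  invisible(paths)
}

#' Read a 4-D series with its scheme sidecars
#'
#' Validates that the sidecar lengths match the 4th dimension. FSL-style
#' `.bvec` columns are renormalized with a warning when within 1% of unit
#' norm, rejected otherwise.
#'
#' @param nii path to a 4-D NIfTI file.
#' @param bval,bvec,tes sidecar paths; supply `bval` alone for an IVIM
#'   series, `bval` + `bvec` for a tensor series, `tes` (JSON) for a
#'   multi-echo series.
#' @param mask optional NIfTI mask path.
#' @return an [image_series].
#' @export
read_series <- function(nii, bval = NULL, bvec = NULL, tes = NULL,
                        mask = NULL) {
  arr <- array(as.numeric(RNifti::readNifti(nii)),
               dim = dim(RNifti::readNifti(nii)))
  if (length(dim(arr)) != 4L) stop("expected a 4-D series in ", nii)
  nvol <- dim(arr)[4]
  msk <- if (!is.null(mask))
    array(as.numeric(RNifti::readNifti(mask)) > 0, dim(arr)[1:3]) else NULL
  if (!is.null(tes)) {
    te <- unlist(jsonlite::read_json(tes)$echo_times_ms)
    if (length(te) != nvol)
      stop(sprintf("%s lists %d echoes but %s has %d volumes",
                   tes, length(te), nii, nvol))
    return(image_series(arr, echo_scheme(te), msk))
  }
  if (is.null(bval)) stop("need a .bval (or tes) sidecar")
  b <- scan(bval, quiet = TRUE)
  if (length(b) != nvol)
    stop(sprintf("%s lists %d b-values but %s has %d volumes",
                 bval, length(b), nii, nvol))
  if (is.null(bvec))
    return(image_series(arr, bvalue_scheme(b), msk))
  G <- unname(as.matrix(read.table(bvec)))
  if (nrow(G) != 3L || ncol(G) != nvol)
    stop(sprintf("%s must be 3 x %d (FSL dialect)", bvec, nvol))
  dir_cols <- which(b > 0)
  D <- unname(t(G[, dir_cols, drop = FALSE]))
  nrm <- sqrt(rowSums(D^2))
  if (any(abs(nrm - 1) > 0.01))
    stop(sprintf("%s has a direction %.3f from unit norm (> 1%%)", bvec,
                 max(abs(nrm - 1))))
  if (any(abs(nrm - 1) > 1e-6)) {
    warning("renormalizing gradient directions (within 1% of unit norm)")
    D <- D / nrm
  }
  bh <- unique(b[dir_cols])
  if (length(bh) != 1L) stop("expected a single nonzero shell in ", bval)
  image_series(arr, gradient_scheme(D, b_low = 0, b_high = bh), msk)
}

#' Serialize an ROI set to JSON
#'
#' @param rois an `roi_set`.
#' @param path output path.
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(lapply(rois, function(r) list(
    slice = r$slice_index, center = r$center, radius = r$radius,
    pixels = unname(as.data.frame(.roi_pixels(r, c(Inf, Inf)))))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  structure(lapply(jsonlite::read_json(path), function(r)
    roi_spec(r$slice, unlist(r$center), r$radius)), class = "roi_set")
}

#' Pipeline configuration
#'
#' All knobs of the end-to-end run, serializable to/from JSON. Defaults
#' reproduce the three acquisition protocols (11 b-values 0-800 s/mm^2,
#' b = 0/500 s/mm^2 on 12 directions, 9 echoes 2.57-24.25 ms), a 10 + 10
#' cohort at SNR 50 Rician noise and the six-ROI protocol.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param n_control,n_model group sizes.
#' @param snr signal-to-noise ratio at b = 0 / first echo.
#' @param noise_kind `"rician"`, `"gaussian"` or `"none"`.
#' @param grid_shape,liver_radius phantom geometry.
#' @param cv within-animal voxel coefficient of variation.
#' @param jitter_px observer-2 ROI jitter for the ICC table.
#' @param b_values,echo_times scheme overrides.
#' @export
pipeline_config <- function(seed = 1L, n_control = 10L, n_model = 10L,
                            snr = 50, noise_kind = "rician",
                            grid_shape = c(20L, 20L, 5L), liver_radius = 7,
                            cv = 0.05, jitter_px = 2,
                            b_values = c(0, 20, 40, 60, 80, 100, 150, 200,
                                         400, 600, 800),
                            echo_times = NULL) {
  structure(list(seed = as.integer(seed), n_control = as.integer(n_control),
                 n_model = as.integer(n_model), snr = snr,
                 noise_kind = noise_kind, grid_shape = as.integer(grid_shape),
                 liver_radius = liver_radius, cv = cv, jitter_px = jitter_px,
                 b_values = b_values,
                 echo_times = if (is.null(echo_times)) echo_scheme()$te
                              else echo_times),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config` (for `write_config`).
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}

#' Write a cohort table to CSV
#'
#' @param cohort a `cohort_table` data frame.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(x) <- c("cohort_table", "data.frame")
  x
}
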