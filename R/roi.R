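#' Circular ROI specification
#'
#' A circular region of interest rasterized by center distance: pixel
#' `(i, j)` belongs to the ROI when `(i-cx)^2 + (j-cy)^2 <= radius^2`.
#' The default radius of 2 pixels yields 13 pixels on an integer grid,
#' inside the 12 +/- 2 target of the ROI protocol.
#'
#' @param slice_index slice the ROI lives on.
#' @param center length-2 integer pixel coordinates.
#' @param radius radius in pixels.
#' @export
roi_spec <- function(slice_index, center, radius = 2) {
  structure(list(slice_index = as.integer(slice_index),
                 center = as.numeric(center), radius = radius),
            class = "roi_spec")
}

.roi_pixels <- function(roi, grid_shape) {
  r <- ceiling(roi$radius)
  xs <- (roi$center[1] - r):(roi$center[1] + r)
  ys <- (roi$center[2] - r):(roi$center[2] + r)
  g <- expand.grid(x = xs, y = ys)
  g <- g[(g$x - roi$center[1])^2 + (g$y - roi$center[2])^2 <= roi$radius^2, ]
  g <- g[g$x >= 1 & g$x <= grid_shape[1] & g$y >= 1 & g$y <= grid_shape[2], ]
  cbind(g$x, g$y)
}

.roi_ok <- function(roi, layout) {
  px <- .roi_pixels(roi, layout$grid_shape)
  if (nrow(px) == 0) return(FALSE)
  z <- roi$slice_index
  all(layout$liver_mask[cbind(px, z)]) && !any(layout$vessel_mask[cbind(px, z)])
}

.rois_overlap <- function(a, b) {
  a$slice_index == b$slice_index &&
    sum((a$center - b$center)^2) <= (a$radius + b$radius)^2
}

#' Place the six-ROI protocol on a phantom
#'
#' Emulates the manual protocol with constrained random placement: six
#' circular ROIs, two per slice on the three central liver slices, each
#' fully inside the liver mask, not touching the vessel mask, pairwise
#' non-overlapping. Deterministic for a fixed seed.
#'
#' @param layout a [phantom_layout].
#' @param seed integer seed.
#' @param radius ROI radius in pixels.
#' @param n_per_slice ROIs per slice (6 ROIs / 3 slices by default).
#' @param max_tries placement retries before giving up.
#' @return object of class `"roi_set"`: list of six [roi_spec]s.
#' @export
place_rois <- function(layout, seed = 1L, radius = 2, n_per_slice = 2L,
                       max_tries = 500L) {
  stopifnot(inherits(layout, "phantom_layout"))
  set.seed(seed)
  sl <- layout$liver_slices
  nz <- sl[vapply(sl, function(z) any(layout$liver_mask[, , z]), logical(1))]
  if (length(nz) < 3L) stop("liver mask nonempty on fewer than 3 slices")
  mid <- nz[seq(floor((length(nz) - 3) / 2) + 1, length.out = 3)]
  rois <- list()
  for (z in mid) {
    cand <- which(layout$liver_mask[, , z], arr.ind = TRUE)
    placed <- 0L
    for (try in seq_len(max_tries)) {
      ct <- cand[sample.int(nrow(cand), 1L), ]
      roi <- roi_spec(z, ct, radius)
      if (!.roi_ok(roi, layout)) next
      if (any(vapply(rois, .rois_overlap, logical(1), b = roi))) next
      rois[[length(rois) + 1L]] <- roi
      placed <- placed + 1L
      if (placed == n_per_slice) break
    }
    if (placed < n_per_slice)
      stop(sprintf("could not place %d non-overlapping ROIs on slice %d",
                   n_per_slice, z))
  }
  structure(rois, class = "roi_set")
}

#' Two simulated observers
#'
#' Returns two ROI sets: the first from [place_rois()], the second a
#' jittered copy whose centers are displaced by at most `jitter_px` pixels
#' while still satisfying every placement constraint. With
#' `jitter_px = 0` the two sets are identical (downstream ICC = 1).
#'
#' @param layout a [phantom_layout].
#' @param jitter_px maximum center displacement in pixels, >= 0.
#' @param seed integer seed.
#' @param radius ROI radius.
#' @return list with elements `obs1`, `obs2`, each an `roi_set`.
#' @export
simulate_observers <- function(layout, jitter_px = 2, seed = 1L, radius = 2) {
  stopifnot(jitter_px >= 0)
  obs1 <- place_rois(layout, seed = seed, radius = radius)
  if (jitter_px == 0) return(list(obs1 = obs1, obs2 = obs1))
  set.seed(seed + 99991L)
  obs2 <- list()
  for (roi in obs1) {
    done <- FALSE
    for (try in 1:200) {
      off <- round(runif(2, -jitter_px, jitter_px))
      if (sum(off^2) > jitter_px^2) next
      cand <- roi_spec(roi$slice_index, roi$center + off, roi$radius)
      if (!.roi_ok(cand, layout)) next
      obs2[[length(obs2) + 1L]] <- cand
      done <- TRUE
      break
    }
    if (!done) stop("jitter pushed an ROI outside the admissible region")
  }
  list(obs1 = obs1, obs2 = structure(obs2, class = "roi_set"))
}

#' Animal-level value from a parametric map
#'
#' Per-ROI means are taken over the ROI's pixels (voxels flagged invalid,
#' i.e. `NA`, are excluded); the animal-level value is the unweighted mean
#' of the per-ROI means. An ROI with no valid pixel is dropped with a
#' flag; if every ROI is fully invalid an error is raised.
#'
#' @param map 3-D numeric array (a parameter map; `NA` marks invalid
#'   voxels).
#' @param rois an `roi_set` from [place_rois()].
#' @return list with `value` (mean of ROI means), `roi_means`, `n_used`,
#'   `dropped` (indices of fully invalid ROIs).
#' @export
extract_roi_means <- function(map, rois) {
  ms <- vapply(rois, function(roi) {
    px <- .roi_pixels(roi, dim(map))
    mean(map[cbind(px, roi$slice_index)], na.rm = TRUE)
  }, numeric(1))
  dropped <- which(is.nan(ms))
  keep <- ms[!is.nan(ms)]
  if (!length(keep)) stop("every ROI lies entirely on invalid voxels")
  list(value = mean(keep), roi_means = ms, n_used = length(keep),
       dropped = dropped)
}
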