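test_that("forced placement returns exactly the admissible discs", {
  # liver mask = six disjoint discs, two per slice on three slices
  liver <- array(FALSE, c(24, 24, 5))
  centers <- list(c(6, 6), c(18, 18), c(6, 18), c(18, 6), c(6, 12), c(18, 12))
  slices <- c(2, 2, 3, 3, 4, 4)
  for (k in seq_along(centers)) {
    cx <- centers[[k]][1]; cy <- centers[[k]][2]
    for (i in (cx - 2):(cx + 2)) for (j in (cy - 2):(cy + 2))
      if ((i - cx)^2 + (j - cy)^2 <= 4) liver[i, j, slices[k]] <- TRUE
  }
  lay <- phantom_layout_from_masks(liver)
  rois <- place_rois(lay, seed = 1)
  expect_length(rois, 6L)
  got <- lapply(rois, function(r) c(r$slice_index, r$center))
  want <- Map(c, slices, centers)
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(want, paste, collapse = ","))
})

test_that("placement respects masks, overlap and seeding", {
  lay <- phantom_layout()
  r1 <- place_rois(lay, seed = 5)
  r2 <- place_rois(lay, seed = 5)
  r3 <- place_rois(lay, seed = 6)
  expect_identical(r1, r2)                     # deterministic per seed
  expect_false(identical(r1, r3))              # seeded variation
  # the 12 +/- 2 pixel contract for the default radius
  px <- vapply(r1, function(r)
    nrow(liverqmr:::.roi_pixels(r, lay$grid_shape)), integer(1))
  expect_true(all(px >= 10 & px <= 14))
  expect_equal(length(unique(vapply(r1, `[[`, integer(1), "slice_index"))), 3L)
  # vessel avoidance over many seeds
  for (s in 1:100) {
    rs <- place_rois(lay, seed = s)
    for (r in rs) {
      p <- liverqmr:::.roi_pixels(r, lay$grid_shape)
      expect_false(any(lay$vessel_mask[cbind(p, r$slice_index)]))
    }
  }
})

test_that("ROI means are linear and handle invalid voxels", {
  lay <- phantom_layout()
  rois <- place_rois(lay, seed = 2)
  dm <- lay$grid_shape
  const <- array(3.7, dm)
  expect_equal(extract_roi_means(const, rois)$value, 3.7)
  # map equal to the slice index: value = mean of the three slice indices
  smap <- array(rep(seq_len(dm[3]), each = dm[1] * dm[2]), dm)
  sl <- vapply(rois, `[[`, integer(1), "slice_index")
  expect_equal(extract_roi_means(smap, rois)$value, mean(unique(sl)))
  # linearity
  set.seed(4)
  m1 <- array(rnorm(prod(dm)), dm); m2 <- array(rnorm(prod(dm)), dm)
  v <- function(m) extract_roi_means(m, rois)$value
  expect_equal(v(2 * m1 + 3 * m2), 2 * v(m1) + 3 * v(m2))
  # an all-invalid ROI is dropped and flagged
  holed <- const
  p <- liverqmr:::.roi_pixels(rois[[1]], dm)
  holed[cbind(p, rois[[1]]$slice_index)] <- NA
  r <- extract_roi_means(holed, rois)
  expect_equal(r$n_used, 5L)
  expect_equal(r$dropped, 1L)
  expect_equal(r$value, 3.7)
  expect_error(extract_roi_means(array(NA_real_, dm), rois), "invalid")
})

test_that("simulated observers coincide at zero jitter and diverge after", {
  lay <- phantom_layout()
  o0 <- simulate_observers(lay, jitter_px = 0, seed = 3)
  expect_identical(o0$obs1, o0$obs2)
  o2 <- simulate_observers(lay, jitter_px = 2, seed = 3)
  d <- vapply(seq_along(o2$obs1), function(i)
    sqrt(sum((o2$obs1[[i]]$center - o2$obs2[[i]]$center)^2)), numeric(1))
  expect_true(all(d <= 2 + 1e-9))
  for (r in o2$obs2) expect_true(liverqmr:::.roi_ok(r, lay))
})

test_that("observer jitter degrades agreement on a heterogeneous map", {
  lay <- phantom_layout()
  set.seed(10)
  n_animal <- 12
  vals <- function(jit) {
    sapply(seq_len(n_animal), function(i) {
      truth <- 100 + 10 * i                     # between-animal spread
      m <- array(NA_real_, lay$grid_shape)
      m[lay$liver_mask] <- truth * (1 + 0.08 * rnorm(sum(lay$liver_mask)))
      o <- simulate_observers(lay, jitter_px = jit, seed = 100 + i)
      c(extract_roi_means(m, o$obs1)$value, extract_roi_means(m, o$obs2)$value)
    })
  }
  v0 <- vals(0); v2 <- vals(2)
  expect_equal(icc_two_way(v0[1, ], v0[2, ])$icc, 1)
  expect_lt(icc_two_way(v2[1, ], v2[2, ])$icc, 1)
})
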