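test_that("degenerate scales reproduce the group means exactly", {
  ctrl <- default_group_spec("control")
  ctrl$param_sds[] <- 0
  coh <- sample_cohort(ctrl, default_group_spec("model"), seed = 7)
  pfc <- coh$pf[coh$group == "control"]
  expect_equal(pfc, rep(0.3044, 10))            # PF = 30.44% for every animal
  expect_equal(coh$r2star[coh$group == "control"], rep(88.89, 10))
})

test_that("independent variables stay uncorrelated and targets are hit", {
  v <- c(liverqmr:::.cohort_vars, liverqmr:::.score_vars)
  # identity dependence: sample rank correlations near 0 at large n
  id <- diag(length(v)); dimnames(id) <- list(v, v)
  big <- group_spec("control", 4000,
                    default_group_spec("control")$param_means,
                    default_group_spec("control")$param_sds,
                    list(i_score = c(`0` = 0.5, `1` = 0.5),
                         f_score = c(`0` = 0.5, `1` = 0.5)),
                    dependence = id)
  x <- liverqmr:::.sample_group(big, seed = 3)
  r <- cor(x$mda, x$mpo, method = "spearman")
  expect_lt(abs(r), 3 / sqrt(4000))
  # a strong target is achieved through the copula calibration
  dep <- id; dep["mda", "mpo"] <- dep["mpo", "mda"] <- 0.9
  big$dependence <- dep; big$n <- 10000L
  y <- liverqmr:::.sample_group(big, seed = 4)
  expect_equal(cor(y$mda, y$mpo, method = "spearman"), 0.9,
               tolerance = 0.025)
})

test_that("marginal means are recovered within 1% at large n", {
  for (g in c("control", "model")) {
    spec <- default_group_spec(g, n = 10000)
    x <- liverqmr:::.sample_group(spec, seed = 9)
    for (v in c("dslow", "dfast", "pf", "md", "fa", "r2star"))
      expect_equal(mean(x[[v]]), unname(spec$param_means[[v]]),
                   tolerance = 0.01)
  }
})

test_that("generated parameters respect the physical invariants", {
  coh <- sample_cohort(seed = 123)
  expect_true(all(coh$pf > 0 & coh$pf < 1))
  expect_true(all(coh$dfast > coh$dslow))
  expect_true(all(coh$r2star > 0))
  expect_true(all(coh$fa >= 0 & coh$fa <= 1))
  expect_true(all(coh$i_score >= 0 & coh$i_score == round(coh$i_score)))
  # control animals score 0 on both histology scales
  expect_true(all(coh$i_score[coh$group == "control"] == 0))
})

test_that("a non-PSD dependence matrix is rejected with its eigenvalue", {
  v <- c(liverqmr:::.cohort_vars, liverqmr:::.score_vars)
  bad <- diag(length(v)); dimnames(bad) <- list(v, v)
  bad["dslow", "dfast"] <- bad["dfast", "dslow"] <- 0.95
  bad["dfast", "pf"] <- bad["pf", "dfast"] <- 0.95
  bad["dslow", "pf"] <- bad["pf", "dslow"] <- -0.95
  spec <- default_group_spec("control")
  spec$dependence <- bad
  expect_error(sample_cohort(spec, default_group_spec("model"), seed = 1),
               "positive semidefinite.*eigenvalue")
  # the shipped default has already been projected to validity
  P <- 2 * sin(pi * default_dependence() / 6)
  expect_gte(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values),
             -1e-9)
})

test_that("rendering is deterministic and honours the noise model", {
  lay <- tiny_layout()
  rec <- list(dslow = 1.2e-3, dfast = 30e-3, pf = 0.28, md = 1.6e-3,
              fa = 0.35, r2star = 95)
  a1 <- render_animal(rec, lay, noise = noise_model("rician", 50, seed = 77))
  a2 <- render_animal(rec, lay, noise = noise_model("rician", 50, seed = 77))
  expect_identical(a1$ivim$data, a2$ivim$data)
  expect_identical(a1$bold$data, a2$bold$data)
  # noise-free homogeneous liver: the b = 0 volume is constant in the mask
  a0 <- render_animal(rec, lay, noise = noise_model("none", seed = 1), cv = 0)
  b0 <- a0$ivim$data[, , , 1]
  expect_lt(diff(range(b0[lay$liver_mask])), 1e-12)
  expect_true(all(b0[!lay$liver_mask] == 0))
})

test_that("the background magnitude reproduces the Rayleigh mean", {
  lay <- phantom_layout(grid_shape = c(50, 50, 8), liver_slices = 2:7,
                        liver_radius = 7)
  rec <- list(dslow = 1.2e-3, dfast = 30e-3, pf = 0.28, md = 1.6e-3,
              fa = 0.35, r2star = 95)
  an <- render_animal(rec, lay, noise = noise_model("rician", 50, seed = 13))
  sigma <- 100 / 50
  bg <- an$bold$data[rep(!lay$liver_mask, length(an$bold$scheme$te))]
  expect_gt(length(bg), 1e5)
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.01)
})

test_that("series/scheme mismatches are rejected", {
  lay <- tiny_layout()
  expect_error(image_series(array(0, c(4, 4, 3, 5)), bvalue_scheme(),
                            lay$liver_mask), "does not match")
  expect_error(noise_model("rician", snr = -1), "snr")
  expect_error(phantom_layout(liver_slices = 2:3), "3 slices")
})
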