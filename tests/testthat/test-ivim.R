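test_that("bi-exponential forward model has the expected limits and values", {
  sch <- bvalue_scheme()
  p <- ivim_params(1.29e-3, 32.33e-3, 0.3044, s0 = 2.5)
  s <- ivim_signal(p, sch)
  expect_equal(s[1], 2.5)                       # S(0) = s0
  expect_true(all(diff(s) < 0))                 # strictly decreasing in b
  # degenerate mixture: pf = 0 collapses to a monoexponential
  p0 <- ivim_params(1.2e-3, 30e-3, 0, s0 = 1)
  expect_equal(ivim_signal(p0, sch), exp(-sch$b * 1.2e-3))
  # direct evaluation at the control-group operating point
  pc <- ivim_params(1.29e-3, 32.33e-3, 0.3044, 1)
  expect_equal(ivim_signal(pc, sch)[11], 0.2478, tolerance = 5e-4)
})

test_that("parameter constructors reject invalid physiology", {
  expect_error(ivim_params(2e-3, 1e-3, 0.2), "dslow < dfast")
  expect_error(ivim_params(1e-3, 2e-2, 1.4), "pf")
  expect_error(ivim_params(1e-3, 2e-2, 0.2, s0 = 0), "s0")
  expect_error(ivim_fit(c(NA, rep(1, 10))), "positive and finite")
  expect_error(ivim_fit(rep(1, 5)), "length")
})

test_that("noise-free signals are recovered across a parameter hypercube", {
  sch <- bvalue_scheme()
  grid <- ivim_lhs(100, seed = 42)
  for (i in seq_len(nrow(grid))) {
    p <- ivim_params(grid$dslow[i], grid$dfast[i], grid$pf[i], grid$s0[i])
    f <- ivim_fit(ivim_signal(p, sch), sch)
    expect_equal(coef(f)[["dslow"]], p$dslow, tolerance = 1e-4)
    expect_equal(coef(f)[["dfast"]], p$dfast, tolerance = 1e-4)
    expect_equal(coef(f)[["pf"]], p$pf, tolerance = 1e-4)
    expect_equal(coef(f)[["s0"]], p$s0, tolerance = 1e-4)
  }
})

test_that("a constant signal is flagged degenerate at the dslow floor", {
  f <- ivim_fit(rep(1, 11))
  expect_true(f$degenerate)
  expect_lt(coef(f)[["dslow"]], 2e-5)
})

test_that("the fit agrees with an independent nonlinear LS implementation", {
  skip_if_not_installed("minpack.lm")
  set.seed(3)
  sch <- bvalue_scheme()
  p <- ivim_params(1.1e-3, 28e-3, 0.25, 100)
  y <- ivim_signal(p, sch) + rnorm(11, 0, 0.5)
  f <- ivim_fit(y, sch)
  m <- minpack.lm::nlsLM(
    y ~ s0 * (pf * exp(-b * df) + (1 - pf) * exp(-b * ds)),
    data = data.frame(y = y, b = sch$b),
    start = list(s0 = 100, pf = 0.25, ds = 1e-3, df = 0.03),
    lower = c(1, 0, 1e-5, 5e-3), upper = c(1e4, 0.7, 5e-3, 0.5),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  expect_equal(unname(coef(f)[c("s0", "pf", "dslow", "dfast")]),
               unname(coef(m)), tolerance = 1e-3)
  expect_lte(f$rss, sum(residuals(m)^2) * (1 + 1e-6))
})

test_that("map fitting is constant on a homogeneous noise-free phantom", {
  lay <- tiny_layout()
  rec <- list(dslow = 1.2e-3, dfast = 30e-3, pf = 0.28, md = 1.6e-3,
              fa = 0.35, r2star = 95)
  an <- render_animal(rec, lay, noise = noise_model("none", seed = 1), cv = 0)
  m <- fit_ivim_map(an$ivim, mask = lay$liver_mask & !lay$vessel_mask)
  expect_lt(diff(range(m$pf, na.rm = TRUE)), 1e-6)
  expect_equal(mean(m$dslow, na.rm = TRUE), 1.2e-3, tolerance = 1e-5)
  expect_error(fit_ivim_map(an$ivim, mask = array(FALSE, dim(lay$liver_mask))),
               "empty mask")
})

test_that("vessel voxels make the PF map bimodal and are excludable", {
  lay <- tiny_layout()
  rec <- list(dslow = 1.2e-3, dfast = 30e-3, pf = 0.28, md = 1.6e-3,
              fa = 0.35, r2star = 95)
  an <- render_animal(rec, lay, noise = noise_model("none", seed = 2),
                      cv = 0.05)
  m <- fit_ivim_map(an$ivim)
  expect_true(all(m$pf[lay$vessel_mask] >= 0.6 - 1e-6))
  liver_only <- m$pf[lay$liver_mask & !lay$vessel_mask]
  expect_lt(max(liver_only), 0.6)
  # masking out vessels: liver-mean PF close to the generating value
  expect_equal(mean(liver_only), 0.28, tolerance = 0.01)
})

test_that("pseudodiffusion is intrinsically noisier than true diffusion", {
  set.seed(21)
  sch <- bvalue_scheme()
  p <- ivim_params(1.29e-3, 32.33e-3, 0.3044, 100)
  s <- ivim_signal(p, sch)
  V <- 400; sigma <- 100 / 50
  Y <- matrix(rep(s, each = V), V)
  Y <- sqrt((Y + rnorm(length(Y), 0, sigma))^2 +
              rnorm(length(Y), 0, sigma)^2)
  r <- liverqmr:::.ivim_fit_batch(Y, sch$b)
  relvar <- function(x, mu) var(x) / mu^2
  expect_gt(relvar(r$dfast, p$dfast), relvar(r$dslow, p$dslow))
})
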