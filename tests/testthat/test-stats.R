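test_that("pooled t matches hand computation and summary equivalence holds", {
  r <- independent_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -1.2247, tolerance = 1e-4)
  expect_equal(r$df, 4)
  expect_equal(independent_t(c(5, 6), c(5, 6))$statistic, 0)
  expect_equal(independent_t(c(2, 2), c(2, 2))$statistic, 0)
  expect_error(independent_t(c(2, 2), c(3, 3)), "zero pooled variance")
  # raw-data and summary-statistic routes agree to 1e-12
  set.seed(14)
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1), 5, 2); b <- rnorm(sample(3:12, 1), 6, 3)
    expect_equal(t_from_summaries(mean(a), sd(a), length(a),
                                  mean(b), sd(b), length(b))$statistic,
                 independent_t(a, b)$statistic, tolerance = 1e-12)
  }
})

test_that("summary t reproduces the published group-comparison statistics", {
  expect_equal(t_from_summaries(30.44, 2.80, 10, 19.97, 3.39, 10)$statistic,
               7.533, tolerance = 0.02)
  expect_equal(t_from_summaries(32.33, 8.87, 10, 22.99, 1.59, 10)$statistic,
               3.276, tolerance = 0.02)
  expect_equal(t_from_summaries(88.89, 12.77, 10, 119.34, 7.53, 10)$statistic,
               -6.496, tolerance = 0.02)
  expect_equal(t_from_summaries(2.06, 0.34, 10, 3.44, 0.43, 10)$statistic,
               -7.950, tolerance = 0.02)
})

test_that("Mann-Whitney U, Z and exact p behave as expected", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)                  # complete separation
  expect_equal(r$z, -1.964, tolerance = 1e-3)   # uncorrected normal approx
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$statistic, 9 / 2)
  expect_equal(mann_whitney(rep(2, 4), rep(2, 5))$p_value, 1)
  # exact p agrees with wilcox.test's exact route (tie-free)
  set.seed(2)
  for (i in 1:10) {
    a <- sample(100, 5); b <- sample(100, 6)
    while (any(a %in% b)) b <- sample(100, 6)
    expect_equal(mann_whitney(a, b, exact = TRUE)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("exact enumeration matches the rank-sum DP oracle on all partitions", {
  pool <- c(3.1, 1.4, 5.9, 2.6, 8.5, 0.3, 7.2, 4.4)
  idx <- utils::combn(8, 4)
  for (j in seq_len(ncol(idx))) {
    a <- pool[idx[, j]]; b <- pool[-idx[, j]]
    expect_equal(mann_whitney(a, b, exact = TRUE)$p_value,
                 ranksum_exact_p(a, b), tolerance = 1e-12)
  }
})

test_that("the normal approximation is close to exact at n = 8/8", {
  set.seed(6)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8, 0.7)
    pe <- mann_whitney(a, b, exact = TRUE)$p_value
    pa <- mann_whitney(a, b, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("ICC(2,1) identities: perfect agreement, offset penalty, CI shape", {
  x <- c(3, 7, 1, 9, 4, 6, 8, 2)
  r <- icc_two_way(x, x)
  expect_equal(r$icc, 1)
  roff <- icc_two_way(x, x + 2)
  expect_lt(roff$icc, 1)                       # absolute agreement penalizes offset
  expect_equal(icc_two_way(x, x + 2, model = "consistency")$icc, 1)
  set.seed(9)
  o1 <- rnorm(20, 50, 10); o2 <- o1 + rnorm(20, 0, 3)
  rr <- icc_two_way(o1, o2)
  expect_true(rr$ci_low <= rr$icc && rr$icc <= rr$ci_high)
  expect_true(rr$icc <= 1)
})

test_that("ICC recovers the variance-components ratio in simulation", {
  set.seed(17)
  reps <- 500
  iccs <- replicate(reps, {
    subj <- rnorm(20, 0, 10)
    icc_two_way(subj + rnorm(20, 0, 3), subj + rnorm(20, 0, 3))$icc
  })
  expect_equal(mean(iccs), 100 / 109, tolerance = 0.02)
})

test_that("correlations match closed forms and flag degenerate input", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1, method = "pearson")$estimate, 1)
  y <- exp(x)
  expect_equal(correlate(x, y, method = "spearman")$estimate, 1)
  expect_lt(correlate(x, y, method = "pearson")$estimate, 1)
  # rank-formula check (values are their own ranks): rho = 1 - 6*4/120
  expect_equal(correlate(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))$estimate, 0.8)
  expect_equal(cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5), method = "spearman"),
               0.8)
  expect_error(correlate(rep(1, 5), 1:5), "zero variance")
  # Spearman equals Pearson on ranks in the tie-free case
  set.seed(3)
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(correlate(a, b, method = "spearman")$estimate,
               correlate(rank(a), rank(b), method = "pearson")$estimate,
               tolerance = 1e-12)
})

test_that("percent change follows the per-animal-vs-control-mean convention", {
  expect_equal(percent_change(c(10, 20), c(15, 15))$mean, 0)
  expect_equal(percent_change(c(10, 20), c(15, 15))$sd, 0)
  p <- percent_change(rep(30.44, 5), 19.97)
  expect_equal(p$mean, 34.40, tolerance = 1e-2)
  expect_equal(percent_change(c(2, 4), c(6, 6), direction = "increase")$mean,
               100)
  expect_error(percent_change(c(-1, 1), 5), "control mean")
})

test_that("the report assembles comparisons, correlations and ICCs", {
  coh <- sample_cohort(seed = 20)
  rep1 <- build_report(coh)
  expect_equal(nrow(rep1$group_comparison), 14)
  expect_equal(nrow(rep1$correlations), 48)    # 6 MR x 8 reference
  expect_true(all(rep1$correlations$p_value >= 0 &
                    rep1$correlations$p_value <= 1))
  mwu_rows <- rep1$group_comparison$test == "mann_whitney"
  expect_true(all(is.finite(rep1$group_comparison$z[mwu_rows])))
  # routing override: everything through Mann-Whitney reports Z everywhere
  all_mwu <- setNames(rep("mann_whitney", 14), names(default_routing()))
  rep2 <- build_report(coh, routing = all_mwu)
  expect_true(all(is.finite(rep2$group_comparison$z)))
  # single-group cohort: no comparison table, correlations still present
  solo <- coh[coh$group == "model", ]
  rep3 <- build_report(solo)
  expect_null(rep3$group_comparison)
  expect_equal(nrow(rep3$correlations), 48)
  # missing variables are dropped with a warning
  expect_warning(build_report(coh[, setdiff(names(coh), "mda")]), "mda")
})
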