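# Independent oracles and small fixtures shared across tests.

# Exact Mann-Whitney null distribution for tie-free data via the shift
# (dynamic-programming) algorithm over rank sums: count[w] = number of
# n1-subsets of ranks 1..n with sum w. Independent of the package's
# value-enumeration route.
ranksum_counts <- function(n1, n2) {
  n <- n1 + n2
  wmax <- sum((n - n1 + 1):n)
  cnt <- matrix(0, n1 + 1, wmax + 1)   # cnt[k+1, w+1]
  cnt[1, 1] <- 1
  for (r in 1:n) {
    for (k in min(r, n1):1) {
      w <- seq(r, wmax)
      cnt[k + 1, w + 1] <- cnt[k + 1, w + 1] + cnt[k, w - r + 1]
    }
  }
  cnt[n1 + 1, ]
}

# exact two-sided p for U via the DP counts (tie-free only)
ranksum_exact_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cnt <- ranksum_counts(n1, n2)
  us <- (seq_along(cnt) - 1) - n1 * (n1 + 1) / 2   # rank-sum -> U
  keep <- cnt > 0
  p_le <- sum(cnt[keep & us <= u]) / sum(cnt)
  p_ge <- sum(cnt[keep & us >= u]) / sum(cnt)
  min(1, 2 * min(p_le, p_ge))
}

# brute-force IVIM grid search: best residual over a lattice in
# (pf, dslow, dfast) with the optimal s0 per node in closed form
ivim_grid_best <- function(signal, b, n = 50) {
  pf <- seq(0.02, 0.65, length.out = n)
  ds <- exp(seq(log(2e-5), log(4.9e-3), length.out = n))
  df <- exp(seq(log(5.1e-3), log(0.45), length.out = n))
  best <- Inf
  Es <- exp(-outer(ds, b))
  Ef <- exp(-outer(df, b))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      M <- pf[i] * Ef + (1 - pf[i]) * matrix(Es[j, ], n, length(b),
                                             byrow = TRUE)
      s0 <- (M %*% signal) / rowSums(M^2)
      rss <- min(rowSums((as.vector(s0) * M -
                            matrix(signal, n, length(b), byrow = TRUE))^2))
      if (rss < best) best <- rss
    }
  }
  best
}

# tiny layout used where geometry details don't matter
tiny_layout <- function() phantom_layout(grid_shape = c(16, 16, 5),
                                         liver_radius = 5,
                                         vessel_centers = list(c(2, 1)),
                                         vessel_radius = 1.1)

# stratified (Latin-hypercube style) sample of valid IVIM parameters with
# dfast/dslow >= 5
ivim_lhs <- function(n, seed = 1) {
  set.seed(seed)
  u <- function() (sample(n) - runif(n)) / n
  ds <- 10^(-3.6 + 1.2 * u())            # ~2.5e-4 .. 4e-3
  ratio <- 5 + 55 * u()
  df <- pmin(pmax(ds * ratio, 5.5e-3), 0.45)   # inside the fit bounds
  pf <- 0.05 + 0.55 * u()
  s0 <- 0.5 + 1.5 * u()
  data.frame(dslow = ds, dfast = df, pf = pf, s0 = s0)
}
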