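#' IVIM parameter set
#'
#' Container for the intravoxel-incoherent-motion bi-exponential model
#' parameters of one voxel (or one tissue): the true (molecular) diffusion
#' coefficient `dslow`, the pseudodiffusion coefficient `dfast` (both
#' mm^2/s), the perfusion fraction `pf` (dimensionless, in \[0, 1\]) and the
#' unattenuated signal `s0`.
#'
#' @param dslow,dfast diffusion coefficients in mm^2/s, `0 < dslow < dfast`.
#' @param pf perfusion fraction in \[0, 1\].
#' @param s0 signal at b = 0, positive.
#' @return named list of class `"ivim_params"`.
#' @export
ivim_params <- function(dslow, dfast, pf, s0 = 1) {
  stopifnot(is.finite(dslow), is.finite(dfast), is.finite(pf), is.finite(s0))
  if (dslow <= 0 || dfast <= dslow) stop("require 0 < dslow < dfast")
  if (pf < 0 || pf > 1) stop("pf must lie in [0, 1]")
  if (s0 <= 0) stop("s0 must be positive")
  structure(list(dslow = dslow, dfast = dfast, pf = pf, s0 = s0),
            class = "ivim_params")
}

#' Bi-exponential IVIM forward signal
#'
#' Evaluates `S(b) = s0 * (pf * exp(-b*dfast) + (1-pf) * exp(-b*dslow))`
#' over a b-value scheme.
#'
#' @param p an [ivim_params] object.
#' @param scheme a [bvalue_scheme].
#' @return numeric signal vector, one entry per b-value.
#' @export
ivim_signal <- function(p, scheme = bvalue_scheme()) {
  b <- scheme$b
  p$s0 * (p$pf * exp(-b * p$dfast) + (1 - p$pf) * exp(-b * p$dslow))
}

#' IVIM fit options
#'
#' Box constraints and optimizer controls for the bi-exponential fit.
#' Defaults are standard liver ranges. `guard` is the identifiability
#' constraint `dfast >= guard * dslow` preventing compartment label swap.
#'
#' @param dslow_bounds,dfast_bounds,pf_bounds,s0_bounds length-2 numeric
#'   bounds (signals are normalized by S(b=0) before fitting, so `s0` is
#'   dimensionless).
#' @param b_split perfusion-free threshold (s/mm^2) for the segmented prefit.
#' @param guard ratio enforced between `dfast` and `dslow`.
#' @param max_iter,tol Levenberg-Marquardt iteration cap and relative step
#'   tolerance.
#' @export
ivim_fit_options <- function(dslow_bounds = c(1e-5, 5e-3),
                             dfast_bounds = c(5e-3, 0.5),
                             pf_bounds = c(0, 0.7),
                             s0_bounds = c(0.2, 5),
                             b_split = 200,
                             guard = 5,
                             max_iter = 60L,
                             tol = 1e-12) {
  structure(list(dslow_bounds = dslow_bounds, dfast_bounds = dfast_bounds,
                 pf_bounds = pf_bounds, s0_bounds = s0_bounds,
                 b_split = b_split, guard = guard,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "ivim_fit_options")
}

# ---- batched 4x4 SPD solver (Cholesky, vectorized across voxels) ---------
# a: list of the 10 unique entries a11..a44 (each length V); g: V x 4 rhs.
.chol4_solve <- function(a11, a21, a31, a41, a22, a32, a42, a33, a43, a44,
                         g1, g2, g3, g4) {
  tiny <- 1e-300
  l11 <- sqrt(pmax(a11, tiny))
  l21 <- a21 / l11; l31 <- a31 / l11; l41 <- a41 / l11
  l22 <- sqrt(pmax(a22 - l21^2, tiny))
  l32 <- (a32 - l31 * l21) / l22
  l42 <- (a42 - l41 * l21) / l22
  l33 <- sqrt(pmax(a33 - l31^2 - l32^2, tiny))
  l43 <- (a43 - l41 * l31 - l42 * l32) / l33
  l44 <- sqrt(pmax(a44 - l41^2 - l42^2 - l43^2, tiny))
  y1 <- g1 / l11
  y2 <- (g2 - l21 * y1) / l22
  y3 <- (g3 - l31 * y1 - l32 * y2) / l33
  y4 <- (g4 - l41 * y1 - l42 * y2 - l43 * y3) / l44
  x4 <- y4 / l44
  x3 <- (y3 - l43 * x4) / l33
  x2 <- (y2 - l32 * x3 - l42 * x4) / l22
  x1 <- (y1 - l21 * x2 - l31 * x3 - l41 * x4) / l11
  cbind(x1, x2, x3, x4)
}

.ivim_project <- function(th, opts) {
  th[, 1] <- pmin(pmax(th[, 1], opts$s0_bounds[1]), opts$s0_bounds[2])
  th[, 2] <- pmin(pmax(th[, 2], opts$pf_bounds[1]), opts$pf_bounds[2])
  th[, 3] <- pmin(pmax(th[, 3], opts$dslow_bounds[1]), opts$dslow_bounds[2])
  th[, 4] <- pmin(pmax(th[, 4], opts$dfast_bounds[1]), opts$dfast_bounds[2])
  low <- th[, 4] < opts$guard * th[, 3]
  if (any(low)) th[low, 4] <- pmax(opts$guard * th[low, 3], opts$dfast_bounds[1])
  th
}

.ivim_model <- function(th, b) {
  Ef <- exp(-outer(th[, 4], b))
  Es <- exp(-outer(th[, 3], b))
  list(m = th[, 1] * (th[, 2] * Ef + (1 - th[, 2]) * Es), Ef = Ef, Es = Es)
}

# Segmented prefit: log-linear over b >= b_split for dslow + intercept
# (-> pf), then a 1-D dfast grid conditional on the other three.
.ivim_segmented <- function(Y, b, opts) {
  V <- nrow(Y)
  hi <- which(b >= opts$b_split)
  if (length(hi) < 2L) hi <- utils::tail(seq_along(b), 2L)
  bh <- b[hi]
  L <- log(pmax(Y[, hi, drop = FALSE], 1e-12))
  xc <- bh - mean(bh)
  slope <- (L %*% xc) / sum(xc^2)
  ds <- pmin(pmax(-as.vector(slope), opts$dslow_bounds[1]), opts$dslow_bounds[2])
  icpt <- rowMeans(L) + ds * mean(bh)
  pf <- pmin(pmax(1 - exp(icpt), opts$pf_bounds[1] + 1e-3, 0.01),
             opts$pf_bounds[2] - 1e-3)
  df_grid <- exp(seq(log(opts$dfast_bounds[1] * 1.01),
                     log(opts$dfast_bounds[2] * 0.99), length.out = 32))
  best <- rep(Inf, V); df <- rep(df_grid[1], V)
  Es <- exp(-outer(ds, b))
  for (dfk in df_grid) {
    M <- pf * matrix(exp(-dfk * b), V, length(b), byrow = TRUE) + (1 - pf) * Es
    sse <- rowSums((M - Y)^2)
    take <- sse < best
    best[take] <- sse[take]; df[take] <- dfk
  }
  .ivim_project(cbind(1, pf, ds, df), opts)
}

# Vectorized box-constrained Levenberg-Marquardt over all voxels at once.
# Y: V x nb signal matrix (raw scale). Returns parameters on the input
# signal scale plus diagnostics.
.ivim_fit_batch <- function(Y, b, opts = ivim_fit_options()) {
  Y <- rbind(Y)
  V <- nrow(Y)
  scale0 <- Y[, 1]
  valid <- apply(Y, 1, function(r) all(is.finite(r)) && all(r > 0))
  out <- list(s0 = rep(NA_real_, V), pf = rep(NA_real_, V),
              dslow = rep(NA_real_, V), dfast = rep(NA_real_, V),
              rss = rep(NA_real_, V), converged = rep(FALSE, V),
              valid = valid)
  if (!any(valid)) return(out)
  Yn <- Y[valid, , drop = FALSE] / scale0[valid]
  th <- .ivim_segmented(Yn, b, opts)
  mod <- .ivim_model(th, b)
  cost <- rowSums((mod$m - Yn)^2)
  lam <- rep(1e-3, nrow(th))
  conv <- rep(FALSE, nrow(th))
  for (it in seq_len(opts$max_iter)) {
    act <- which(!conv)
    if (!length(act)) break
    tha <- th[act, , drop = FALSE]
    Ya <- Yn[act, , drop = FALSE]
    mo <- .ivim_model(tha, b)
    r <- mo$m - Ya
    bE <- function(E) E * matrix(b, nrow(E), length(b), byrow = TRUE)
    J1 <- mo$m / tha[, 1]
    J2 <- tha[, 1] * (mo$Ef - mo$Es)
    J3 <- -tha[, 1] * (1 - tha[, 2]) * bE(mo$Es)
    J4 <- -tha[, 1] * tha[, 2] * bE(mo$Ef)
    a11 <- rowSums(J1 * J1); a21 <- rowSums(J2 * J1); a31 <- rowSums(J3 * J1)
    a41 <- rowSums(J4 * J1); a22 <- rowSums(J2 * J2); a32 <- rowSums(J3 * J2)
    a42 <- rowSums(J4 * J2); a33 <- rowSums(J3 * J3); a43 <- rowSums(J4 * J3)
    a44 <- rowSums(J4 * J4)
    g1 <- rowSums(J1 * r); g2 <- rowSums(J2 * r)
    g3 <- rowSums(J3 * r); g4 <- rowSums(J4 * r)
    la <- lam[act]
    step <- .chol4_solve(a11 * (1 + la), a21, a31, a41,
                         a22 * (1 + la), a32, a42,
                         a33 * (1 + la), a43, a44 * (1 + la),
                         g1, g2, g3, g4)
    cand <- .ivim_project(tha - step, opts)
    mc <- .ivim_model(cand, b)
    cost_c <- rowSums((mc$m - Ya)^2)
    better <- cost_c <= cost[act]
    lam[act] <- ifelse(better, pmax(la / 3, 1e-12), pmin(la * 8, 1e8))
    moved <- rowSums(abs(cand - tha) / (abs(tha) + 1e-12))
    improved <- cost[act] - cost_c
    upd <- act[better]
    if (length(upd)) {
      th[upd, ] <- cand[better, , drop = FALSE]
      cost[upd] <- cost_c[better]
    }
    done <- better & (moved < 1e-9 | improved < opts$tol * (cost[act] + 1e-30))
    conv[act[done]] <- TRUE
  }
  idx <- which(valid)
  out$s0[idx] <- th[, 1] * scale0[idx]
  out$pf[idx] <- th[, 2]
  out$dslow[idx] <- th[, 3]
  out$dfast[idx] <- th[, 4]
  out$rss[idx] <- cost * scale0[idx]^2
  out$converged[idx] <- conv
  # voxels pinned at the dslow floor with no decay are degenerate
  out$degenerate <- !is.na(out$dslow) & out$dslow <= opts$dslow_bounds[1] * 1.0001
  out
}

#' Fit the bi-exponential IVIM model to one voxel
#'
#' Full simultaneous bi-exponential nonlinear least squares over
#' `(s0, pf, dslow, dfast)`, initialized by a segmented prefit (log-linear
#' fit over the high-b tail for `dslow` and the intercept-derived perfusion
#' fraction, then a one-dimensional `dfast` search). The signal is
#' normalized by its b = 0 entry; `s0` is refit jointly to absorb noise in
#' that volume. Optimization is damped Gauss-Newton with box constraints
#' and the identifiability guard `dfast >= guard * dslow`.
#'
#' @param signal positive numeric vector, one entry per b-value.
#' @param scheme a [bvalue_scheme] whose length matches `signal`.
#' @param opts an [ivim_fit_options] object.
#' @return object of class `"ivim_fit"` with elements `params`
#'   ([ivim_params]), `rss`, `converged`, `degenerate`, `scheme`, `signal`.
#' @examples
#' p <- ivim_params(dslow = 1.04e-3, dfast = 22.99e-3, pf = 0.1997)
#' s <- ivim_signal(p)
#' fit <- ivim_fit(s)
#' coef(fit)
#' @export
ivim_fit <- function(signal, scheme = bvalue_scheme(), opts = ivim_fit_options()) {
  if (length(signal) != length(scheme$b))
    stop("signal length does not match the b-value scheme")
  if (any(!is.finite(signal)) || any(signal <= 0))
    stop("signal must be positive and finite; flag such voxels invalid upstream")
  r <- .ivim_fit_batch(matrix(signal, nrow = 1), scheme$b, opts)
  structure(list(
    params = ivim_params(r$dslow, r$dfast, max(r$pf, 1e-12), r$s0),
    rss = r$rss, converged = r$converged, degenerate = r$degenerate,
    scheme = scheme, signal = signal, opts = opts), class = "ivim_fit")
}

#' @export
coef.ivim_fit <- function(object, ...) {
  with(object$params, c(dslow = dslow, dfast = dfast, pf = pf, s0 = s0))
}

#' @export
predict.ivim_fit <- function(object, scheme = object$scheme, ...) {
  ivim_signal(object$params, scheme)
}

#' @export
residuals.ivim_fit <- function(object, ...) {
  object$signal - predict(object)
}

#' @export
print.ivim_fit <- function(x, ...) {
  cat("IVIM bi-exponential fit\n")
  cat(sprintf("  dslow = %.4g mm^2/s, dfast = %.4g mm^2/s, PF = %.1f%%, s0 = %.4g\n",
              x$params$dslow, x$params$dfast, 100 * x$params$pf, x$params$s0))
  cat(sprintf("  rss = %.3g, converged = %s%s\n", x$rss, x$converged,
              if (isTRUE(x$degenerate)) ", DEGENERATE (no decay)" else ""))
  invisible(x)
}

#' Voxelwise IVIM parametric maps
#'
#' Applies the bi-exponential fit to every voxel inside a mask of a 4-D
#' series and returns Dslow, Dfast and PF maps plus within-mask summary
#' statistics. Voxels with non-positive or non-finite signal are marked
#' invalid (`NA` in the maps).
#'
#' @param series an [image_series] whose scheme is a [bvalue_scheme].
#' @param mask logical 3-D array; defaults to the series' liver mask.
#' @param opts an [ivim_fit_options] object.
#' @return list of class `"ivim_maps"`: 3-D arrays `dslow`, `dfast`, `pf`,
#'   logical `valid`, and a `stats` data frame (mean/sd per parameter
#'   inside the mask).
#' @export
fit_ivim_map <- function(series, mask = series$liver_mask,
                         opts = ivim_fit_options()) {
  stopifnot(inherits(series$scheme, "bvalue_scheme"))
  if (!any(mask)) stop("empty mask")
  dm <- dim(series$data)
  idx <- which(mask)
  Y <- matrix(series$data, prod(dm[1:3]), dm[4])[idx, , drop = FALSE]
  r <- .ivim_fit_batch(Y, series$scheme$b, opts)
  mk <- function(v) { a <- array(NA_real_, dm[1:3]); a[idx] <- v; a }
  maps <- list(dslow = mk(r$dslow), dfast = mk(r$dfast), pf = mk(r$pf))
  ok <- r$valid & !r$degenerate
  st <- data.frame(
    parameter = c("dslow", "dfast", "pf"),
    mean = c(mean(r$dslow[ok]), mean(r$dfast[ok]), mean(r$pf[ok])),
    sd = c(stats::sd(r$dslow[ok]), stats::sd(r$dfast[ok]), stats::sd(r$pf[ok])),
    n_valid = sum(ok), n_invalid = sum(!r$valid), n_degenerate = sum(r$degenerate))
  structure(c(maps, list(valid = mk(as.numeric(ok)) > 0, stats = st)),
            class = "ivim_maps")
}
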