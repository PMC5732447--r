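#' Relaxation parameters
#'
#' Monoexponential transverse decay parameters of one voxel: the
#' extrapolated signal `s0` at TE = 0 and the effective relaxation rate
#' `r2star` in 1/s; `t2star = 1000 / r2star` in ms, so the unit invariant
#' `t2star[ms] * r2star[1/s] = 1000` always holds.
#'
#' @param r2star decay rate in 1/s, positive.
#' @param s0 signal at TE = 0, positive.
#' @export
relax_params <- function(r2star, s0 = 1) {
  stopifnot(is.finite(r2star), is.finite(s0))
  if (r2star <= 0) stop("r2star must be positive")
  if (s0 <= 0) stop("s0 must be positive")
  structure(list(s0 = s0, r2star = r2star, t2star = 1000 / r2star),
            class = "relax_params")
}

#' Monoexponential decay signal
#'
#' `S(TE) = s0 * exp(-TE * R2*)` with TE in ms and R2* in 1/s.
#'
#' @param p a [relax_params] object.
#' @param scheme an [echo_scheme].
#' @return positive, strictly decreasing signal vector.
#' @export
decay_signal <- function(p, scheme = echo_scheme()) {
  p$s0 * exp(-(scheme$te / 1000) * p$r2star)
}

# Batched log-linear fit of ln S on TE. Y: V x n_echo. Non-positive echoes
# are dropped voxelwise when at least 3 positive echoes remain.
.r2star_fit_batch <- function(Y, te_ms, min_r2 = 1e-6) {
  Y <- rbind(Y)
  V <- nrow(Y)
  te <- te_ms / 1000
  out <- list(r2star = rep(NA_real_, V), s0 = rep(NA_real_, V),
              valid = rep(FALSE, V), degenerate = rep(FALSE, V),
              n_used = rep(0L, V))
  allpos <- apply(Y, 1, function(r) all(is.finite(r)) && all(r > 0))
  if (any(allpos)) {
    L <- log(Y[allpos, , drop = FALSE])
    xc <- te - mean(te)
    slope <- as.vector(L %*% xc) / sum(xc^2)
    r2 <- pmax(-slope, min_r2)
    s0 <- exp(rowMeans(L) + r2 * mean(te))
    out$r2star[allpos] <- r2
    out$s0[allpos] <- s0
    out$valid[allpos] <- TRUE
    out$degenerate[allpos] <- r2 <= min_r2 * 1.0001
    out$n_used[allpos] <- length(te)
  }
  for (i in which(!allpos)) {
    y <- Y[i, ]
    keep <- is.finite(y) & y > 0
    if (sum(keep) < 3L) next
    f <- stats::lm.fit(cbind(1, te[keep]), log(y[keep]))
    r2 <- max(-f$coefficients[2], min_r2)
    out$r2star[i] <- r2
    out$s0[i] <- exp(f$coefficients[1])
    out$valid[i] <- TRUE
    out$degenerate[i] <- r2 <= min_r2 * 1.0001
    out$n_used[i] <- sum(keep)
  }
  out
}

#' Fit the monoexponential R2* decay to one voxel
#'
#' Default estimator is log-linear least squares of `ln S` against TE,
#' exact on noise-free data. `method = "nls"` adds a Gauss-Newton
#' refinement on the untransformed signal, more robust at low SNR where
#' the log transform reweights late echoes.
#'
#' @param signal positive vector, one entry per echo. Echoes with
#'   non-positive signal are dropped when at least 3 usable echoes remain.
#' @param scheme an [echo_scheme].
#' @param method `"loglin"` (default) or `"nls"`.
#' @return object of class `"r2star_fit"` with `params` ([relax_params]),
#'   `degenerate`, `n_used`, `signal`, `scheme`.
#' @examples
#' s <- decay_signal(relax_params(r2star = 119.34, s0 = 100))
#' r2star_fit(s)
#' @export
r2star_fit <- function(signal, scheme = echo_scheme(),
                       method = c("loglin", "nls")) {
  method <- match.arg(method)
  if (length(signal) != length(scheme$te))
    stop("signal length does not match the echo scheme")
  r <- .r2star_fit_batch(matrix(signal, nrow = 1), scheme$te)
  if (!r$valid[1])
    stop("fewer than 3 positive echoes; voxel invalid")
  r2 <- r$r2star[1]; s0 <- r$s0[1]
  if (method == "nls" && !r$degenerate[1]) {
    te <- scheme$te / 1000
    keep <- is.finite(signal) & signal > 0
    for (it in 1:50) {
      m <- s0 * exp(-te[keep] * r2)
      res <- signal[keep] - m
      J <- cbind(m / s0, -te[keep] * m)
      step <- tryCatch(solve(crossprod(J), crossprod(J, res)),
                       error = function(e) c(0, 0))
      s0 <- max(s0 + step[1], 1e-12)
      r2 <- max(r2 + step[2], 1e-6)
      if (sum(abs(step)) < 1e-10 * (abs(s0) + abs(r2))) break
    }
  }
  structure(list(params = relax_params(r2star = r2, s0 = s0),
                 degenerate = r$degenerate[1], n_used = r$n_used[1],
                 method = method, signal = signal, scheme = scheme),
            class = "r2star_fit")
}

#' @export
coef.r2star_fit <- function(object, ...) {
  with(object$params, c(r2star = r2star, t2star = t2star, s0 = s0))
}

#' @export
predict.r2star_fit <- function(object, scheme = object$scheme, ...) {
  decay_signal(object$params, scheme)
}

#' @export
residuals.r2star_fit <- function(object, ...) object$signal - predict(object)

#' @export
print.r2star_fit <- function(x, ...) {
  cat("Monoexponential R2* fit (", x$method, ")\n", sep = "")
  cat(sprintf("  R2* = %.4g 1/s  (T2* = %.4g ms), s0 = %.4g, echoes used = %d%s\n",
              x$params$r2star, x$params$t2star, x$params$s0, x$n_used,
              if (isTRUE(x$degenerate)) ", DEGENERATE (no decay)" else ""))
  invisible(x)
}

#' Voxelwise R2* and T2* maps
#'
#' @param series an [image_series] whose scheme is an [echo_scheme].
#' @param mask logical 3-D array; defaults to the series' liver mask.
#' @return list of class `"r2star_maps"`: arrays `r2star` (1/s), `t2star`
#'   (ms), logical `valid`, and a `stats` data frame.
#' @export
fit_r2star_map <- function(series, mask = series$liver_mask) {
  stopifnot(inherits(series$scheme, "echo_scheme"))
  if (!any(mask)) stop("empty mask")
  dm <- dim(series$data)
  idx <- which(mask)
  Y <- matrix(series$data, prod(dm[1:3]), dm[4])[idx, , drop = FALSE]
  r <- .r2star_fit_batch(Y, series$scheme$te)
  mk <- function(v) { a <- array(NA_real_, dm[1:3]); a[idx] <- v; a }
  ok <- r$valid & !r$degenerate
  st <- data.frame(parameter = c("r2star", "t2star"),
                   mean = c(mean(r$r2star[ok]), mean(1000 / r$r2star[ok])),
                   sd = c(stats::sd(r$r2star[ok]), stats::sd(1000 / r$r2star[ok])),
                   n_valid = sum(ok), n_invalid = sum(!r$valid),
                   n_degenerate = sum(r$degenerate))
  structure(list(r2star = mk(r$r2star), t2star = mk(1000 / r$r2star),
                 valid = mk(as.numeric(ok)) > 0, stats = st),
            class = "r2star_maps")
}
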