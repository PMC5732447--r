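#' Diffusion tensor container and derived metrics
#'
#' A symmetric 3x3 diffusion tensor stored by its six unique elements
#' (mm^2/s), with eigenvalues and the derived mean diffusivity (MD) and
#' fractional anisotropy (FA).
#'
#' @param dxx,dyy,dzz,dxy,dxz,dyz tensor elements in mm^2/s.
#' @return object of class `"diffusion_tensor"` with the element vector,
#'   eigenvalues (descending), `md` and `fa`.
#' @examples
#' t_iso <- diffusion_tensor(1.76e-3, 1.76e-3, 1.76e-3, 0, 0, 0)
#' t_iso$md   # 1.76e-3
#' t_iso$fa   # 0
#' @export
diffusion_tensor <- function(dxx, dyy, dzz, dxy = 0, dxz = 0, dyz = 0) {
  M <- matrix(c(dxx, dxy, dxz, dxy, dyy, dyz, dxz, dyz, dzz), 3, 3)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  clamped <- any(ev < 0)
  ev <- pmax(ev, 0)
  m <- tensor_metrics_eig(ev)
  structure(list(elements = c(dxx = dxx, dyy = dyy, dzz = dzz,
                              dxy = dxy, dxz = dxz, dyz = dyz),
                 matrix = M, eigenvalues = ev, md = m[["md"]], fa = m[["fa"]],
                 clamped = clamped),
            class = "diffusion_tensor")
}

#' Axially symmetric tensor from MD and FA
#'
#' Builds a prolate tensor with prescribed mean diffusivity and fractional
#' anisotropy, principal axis along `axis`. Used by the phantom renderer.
#' For eigenvalues `md*(1+2*delta), md*(1-delta), md*(1-delta)` the FA
#' identity gives `delta = fa * sqrt(3 / (9 - 6*fa^2))`.
#'
#' @param md mean diffusivity (mm^2/s), positive.
#' @param fa fractional anisotropy in \[0, 1\].
#' @param axis principal direction (any nonzero 3-vector).
#' @export
tensor_from_md_fa <- function(md, fa, axis = c(1, 0, 0)) {
  stopifnot(md > 0, fa >= 0, fa <= 1)
  delta <- fa * sqrt(3 / (9 - 6 * fa^2))
  lam <- md * c(1 + 2 * delta, 1 - delta, 1 - delta)
  u <- axis / sqrt(sum(axis^2))
  # complete an orthonormal frame
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- v - sum(v * u) * u; e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(u[2] * e2[3] - u[3] * e2[2],
          u[3] * e2[1] - u[1] * e2[3],
          u[1] * e2[2] - u[2] * e2[1])
  R <- cbind(u, e2, e3)
  M <- R %*% diag(lam) %*% t(R)
  diffusion_tensor(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
}

# MD/FA from an eigenvalue triple (vector form used everywhere internally)
tensor_metrics_eig <- function(ev) {
  md <- mean(ev)
  ss <- sum(ev^2)
  fa <- if (ss == 0) 0 else sqrt(1.5 * sum((ev - md)^2) / ss)
  c(md = md, fa = min(max(fa, 0), 1))
}

#' MD and FA of a fitted tensor
#'
#' Mean diffusivity is the eigenvalue mean (trace/3); fractional anisotropy
#' is the normalized eigenvalue dispersion
#' `sqrt(3/2) * sqrt(sum((lambda - MD)^2)) / sqrt(sum(lambda^2))`, clipped
#' to \[0, 1\]. An all-zero tensor yields `(0, 0)`.
#'
#' @param t a [diffusion_tensor].
#' @return named numeric vector `c(md =, fa =)`.
#' @export
tensor_metrics <- function(t) {
  tensor_metrics_eig(t$eigenvalues)
}

#' Diffusion tensor forward signal
#'
#' `S(g, b) = s0 * exp(-b * g' D g)` over a two-shell scheme: one b_low
#' (usually 0) volume followed by the 12 weighted directions.
#'
#' @param t a [diffusion_tensor] (positive semidefinite).
#' @param s0 unweighted signal.
#' @param scheme a [gradient_scheme].
#' @return numeric vector of length `1 + nrow(directions)`.
#' @export
dti_signal <- function(t, s0 = 1, scheme = gradient_scheme()) {
  g <- scheme$directions
  adc <- rowSums((g %*% t$matrix) * g)
  c(s0 * exp(-scheme$b_low * mean(adc)),
    s0 * exp(-scheme$b_high * adc))
}

# Batched log-linear tensor fit. Y: V x (1 + ndir) positive signals.
# Returns per-voxel tensor elements, eigenvalues, md, fa.
.dti_fit_batch <- function(Y, scheme) {
  Y <- rbind(Y)
  V <- nrow(Y)
  nd <- nrow(scheme$directions)
  stopifnot(ncol(Y) == nd + 1L)
  valid <- apply(Y, 1, function(r) all(is.finite(r)) && all(r > 0))
  X <- -scheme$b_high * dti_design(scheme$directions)    # 12 x 6
  Xp <- solve(crossprod(X), t(X))                        # 6 x 12
  out <- list(md = rep(NA_real_, V), fa = rep(NA_real_, V),
              elements = matrix(NA_real_, V, 6), clamped = rep(FALSE, V),
              valid = valid,
              eigenvalues = matrix(NA_real_, V, 3))
  if (!any(valid)) return(out)
  Yv <- Y[valid, , drop = FALSE]
  L <- log(Yv[, -1, drop = FALSE] / Yv[, 1])             # ln(S/S0)
  D <- L %*% t(Xp)                                       # V x 6
  iv <- which(valid)
  for (k in seq_along(iv)) {
    d <- D[k, ]
    M <- matrix(c(d[1], d[4], d[5], d[4], d[2], d[6], d[5], d[6], d[3]), 3, 3)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    cl <- any(ev < 0)
    ev <- pmax(ev, 0)
    m <- tensor_metrics_eig(ev)
    i <- iv[k]
    out$elements[i, ] <- d
    out$eigenvalues[i, ] <- ev
    out$md[i] <- m[["md"]]; out$fa[i] <- m[["fa"]]; out$clamped[i] <- cl
  }
  out
}

#' Fit the diffusion tensor to one voxel
#'
#' Log-linear least squares of `ln(S/S0)` on the six-column quadratic-form
#' design built from the gradient directions; `S0` is taken from the
#' measured b = 0 volume (single-b0 acquisition), not refit. Negative
#' eigenvalues are clamped to zero and the voxel flagged.
#'
#' @param signal positive vector: b = 0 volume first, then the weighted
#'   directions in scheme order.
#' @param scheme a [gradient_scheme].
#' @return object of class `"dti_fit"` with `tensor` ([diffusion_tensor]),
#'   `md`, `fa`, `clamped`, `signal`, `scheme`.
#' @examples
#' s <- dti_signal(diffusion_tensor(1.46e-3, 1.46e-3, 1.46e-3))
#' fit <- dti_fit(s)
#' c(fit$md, fit$fa)
#' @export
dti_fit <- function(signal, scheme = gradient_scheme()) {
  if (length(signal) != nrow(scheme$directions) + 1L)
    stop("signal length does not match the gradient scheme (expect 1 + ndir)")
  if (any(!is.finite(signal)) || any(signal <= 0))
    stop("signal must be positive and finite; flag such voxels invalid upstream")
  r <- .dti_fit_batch(matrix(signal, nrow = 1), scheme)
  d <- r$elements[1, ]
  structure(list(tensor = diffusion_tensor(d[1], d[2], d[3], d[4], d[5], d[6]),
                 md = r$md[1], fa = r$fa[1], clamped = r$clamped[1],
                 s0 = signal[1], signal = signal, scheme = scheme),
            class = "dti_fit")
}

#' @export
coef.dti_fit <- function(object, ...) {
  c(object$tensor$elements, md = object$md, fa = object$fa)
}

#' @export
predict.dti_fit <- function(object, scheme = object$scheme, ...) {
  dti_signal(object$tensor, s0 = object$s0, scheme = scheme)
}

#' @export
residuals.dti_fit <- function(object, ...) object$signal - predict(object)

#' @export
print.dti_fit <- function(x, ...) {
  cat("Diffusion tensor fit (log-linear LS)\n")
  cat(sprintf("  MD = %.4g mm^2/s, FA = %.4f%s\n", x$md, x$fa,
              if (x$clamped) " [eigenvalue clamped]" else ""))
  invisible(x)
}

#' Voxelwise MD and FA maps
#'
#' @param series an [image_series] whose scheme is a [gradient_scheme].
#' @param mask logical 3-D array; defaults to the series' liver mask.
#' @return list of class `"dti_maps"`: arrays `md`, `fa`, logical `valid`,
#'   `n_clamped`, and a `stats` data frame.
#' @export
fit_dti_map <- function(series, mask = series$liver_mask) {
  stopifnot(inherits(series$scheme, "gradient_scheme"))
  if (!any(mask)) stop("empty mask")
  dm <- dim(series$data)
  idx <- which(mask)
  Y <- matrix(series$data, prod(dm[1:3]), dm[4])[idx, , drop = FALSE]
  r <- .dti_fit_batch(Y, series$scheme)
  mk <- function(v) { a <- array(NA_real_, dm[1:3]); a[idx] <- v; a }
  ok <- r$valid
  st <- data.frame(parameter = c("md", "fa"),
                   mean = c(mean(r$md[ok]), mean(r$fa[ok])),
                   sd = c(stats::sd(r$md[ok]), stats::sd(r$fa[ok])),
                   n_valid = sum(ok), n_invalid = sum(!ok),
                   n_clamped = sum(r$clamped, na.rm = TRUE))
  structure(list(md = mk(r$md), fa = mk(r$fa), valid = mk(as.numeric(ok)) > 0,
                 n_clamped = sum(r$clamped, na.rm = TRUE), stats = st),
            class = "dti_maps")
}
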