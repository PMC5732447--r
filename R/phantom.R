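#' @importFrom stats rnorm pnorm qnorm runif sd cor quantile
NULL

# canonical variable order used by the cohort sampler
.cohort_vars <- c("dslow", "dfast", "pf", "md", "fa", "r2star",
                  "alt", "ast", "ldh", "mda", "mpo", "sod")
.score_vars <- c("i_score", "f_score")

#' Group specification for the synthetic cohort
#'
#' Marginal means/SDs for the six MR parameters (SI units: diffusivities in
#' mm^2/s, PF as a fraction, R2* in 1/s) and six biochemical variables, a
#' discrete distribution over METAVIR-style I and F scores, and a
#' rank-correlation (Spearman) dependence matrix over all 14 variables.
#'
#' @param name group label, `"control"` or `"model"`.
#' @param n animal count, at least 2.
#' @param param_means,param_sds named numeric vectors over
#'   `dslow, dfast, pf, md, fa, r2star, alt, ast, ldh, mda, mpo, sod`.
#' @param score_dist list with elements `i_score`, `f_score`: probability
#'   vectors over scores `0, 1, 2, ...`.
#' @param dependence 14 x 14 symmetric Spearman-target matrix (unit
#'   diagonal, entries in \[-1, 1\]) in the order above followed by
#'   `i_score, f_score`.
#' @return object of class `"group_spec"`.
#' @seealso [default_group_spec()] for the study defaults.
#' @export
group_spec <- function(name, n, param_means, param_sds, score_dist,
                       dependence = default_dependence()) {
  stopifnot(name %in% c("control", "model"), n >= 2)
  miss <- setdiff(.cohort_vars, names(param_means))
  if (length(miss)) stop("param_means missing: ", paste(miss, collapse = ", "))
  if (any(param_sds[.cohort_vars] < 0)) stop("scale parameters must be >= 0")
  if (!isTRUE(all.equal(dependence, t(dependence))) ||
      any(abs(dependence) > 1 + 1e-12) || any(abs(diag(dependence) - 1) > 1e-12))
    stop("dependence must be symmetric with unit diagonal and entries in [-1, 1]")
  for (sv in .score_vars) {
    p <- score_dist[[sv]]
    if (is.null(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("score_dist$", sv, " must be a probability vector")
  }
  structure(list(name = name, n = as.integer(n),
                 param_means = param_means[.cohort_vars],
                 param_sds = param_sds[.cohort_vars],
                 score_dist = score_dist, dependence = dependence),
            class = "group_spec")
}

#' Study-default group specifications
#'
#' Marginal locations and scales for the sham-operated control group and
#' the warm ischemia-reperfusion model group of a 10 + 10 rabbit cohort:
#' mean +/- SD for the normally summarized variables, and for variables
#' summarized as median (IQR) a Gaussian approximation with mean = median
#' and SD = IQR/1.349. Scores are discrete over \{0, 1, 2\} with
#' probabilities matching the reported medians and quartiles (control
#' animals score 0).
#'
#' @param name `"control"` or `"model"`.
#' @param n animals per group (default 10).
#' @param dependence Spearman dependence matrix; see [default_dependence()].
#' @export
default_group_spec <- function(name = c("control", "model"), n = 10,
                               dependence = default_dependence()) {
  name <- match.arg(name)
  if (name == "control") {
    m <- c(dslow = 1.29e-3, dfast = 32.33e-3, pf = 0.3044, md = 1.76e-3,
           fa = 0.36, r2star = 88.89, alt = 34.50, ast = 44.70, ldh = 314.20,
           mda = 2.06, mpo = 14.22, sod = 183.20)
    s <- c(dslow = 0.14e-3, dfast = 8.87e-3, pf = 0.0280, md = 0.20e-3,
           fa = 0.03, r2star = 12.77, alt = (37.00 - 24.75) / 1.349,
           ast = 31.23, ldh = 285.60, mda = 0.34, mpo = 3.87, sod = 20.89)
    sc <- list(i_score = c(`0` = 1), f_score = c(`0` = 1))
  } else {
    m <- c(dslow = 1.04e-3, dfast = 22.99e-3, pf = 0.1997, md = 1.46e-3,
           fa = 0.38, r2star = 119.34, alt = 165.00, ast = 348.00,
           ldh = 1117.00, mda = 3.44, mpo = 19.29, sod = 121.78)
    s <- c(dslow = 0.21e-3, dfast = 1.59e-3, pf = 0.0339, md = 0.14e-3,
           fa = 0.04, r2star = 7.53, alt = (247.75 - 65.00) / 1.349,
           ast = (708.25 - 297.75) / 1.349, ldh = (2024.75 - 789.25) / 1.349,
           mda = 0.43, mpo = 2.84, sod = 11.92)
    sc <- list(i_score = c(`0` = 0.4, `1` = 0.5, `2` = 0.1),
               f_score = c(`0` = 0.5, `1` = 0.4, `2` = 0.1))
  }
  group_spec(name, n, m, s, sc, dependence)
}

# published Spearman correlations: 6 MR rows x 8 reference columns
.table3 <- matrix(c(
  -0.568, -0.513, -0.707, -0.611, -0.514,  0.549, -0.609, -0.441,
  -0.711, -0.600, -0.586, -0.749, -0.676,  0.630, -0.552, -0.451,
  -0.670, -0.662, -0.726, -0.835, -0.760,  0.772, -0.715, -0.471,
  -0.454, -0.542, -0.693, -0.616, -0.460,  0.568, -0.831, -0.631,
   0.024,  0.313,  0.175,  0.316, -0.073, -0.414,  0.139,  0.336,
   0.756,  0.802,  0.680,  0.760,  0.485, -0.792,  0.445,  0.390),
  nrow = 6, byrow = TRUE,
  dimnames = list(c("dslow", "dfast", "pf", "md", "fa", "r2star"),
                  c("alt", "ast", "ldh", "mda", "mpo", "sod",
                    "i_score", "f_score")))

#' Nearest valid correlation matrix
#'
#' Projects a symmetric matrix onto the correlation matrices with smallest
#' eigenvalue at least `eps`, by alternating eigenvalue clipping and
#' unit-diagonal rescaling.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param eps smallest admissible eigenvalue.
#' @export
nearest_psd <- function(R, eps = 1e-6) {
  for (it in 1:100) {
    e <- eigen(R, symmetric = TRUE)
    if (min(e$values) >= eps * 0.999) break
    R <- e$vectors %*% diag(pmax(e$values, eps)) %*% t(e$vectors)
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    R <- (R + t(R)) / 2
  }
  diag(R) <- 1
  R
}

#' Default dependence matrix
#'
#' A 14 x 14 Spearman rank-correlation target over the MR parameters,
#' biochemistry and histology scores. The MR-by-reference block holds the
#' study's published correlations; blocks the study does not print
#' (MR-by-MR, reference-by-reference) start at zero. Because the published
#' pairwise block need not embed in a positive-semidefinite whole, the
#' matrix is mapped to its Gaussian-copula Pearson image
#' (`2*sin(pi*rho/6)`), projected to the nearest valid correlation matrix,
#' and mapped back.
#'
#' @export
default_dependence <- function() {
  v <- c(.cohort_vars, .score_vars)
  R <- diag(length(v)); dimnames(R) <- list(v, v)
  R[rownames(.table3), colnames(.table3)] <- .table3
  R[colnames(.table3), rownames(.table3)] <- t(.table3)
  P <- nearest_psd(2 * sin(pi * R / 6))
  Rb <- (6 / pi) * asin(P / 2)
  diag(Rb) <- 1
  dimnames(Rb) <- list(v, v)
  (Rb + t(Rb)) / 2
}

.sample_group <- function(spec, seed) {
  set.seed(seed)
  R <- 2 * sin(pi * spec$dependence / 6)        # Spearman -> Pearson (copula)
  e <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(e) < -1e-8)
    stop(sprintf(paste0("dependence matrix is not positive semidefinite after ",
                        "copula mapping (smallest eigenvalue %.3g)"), min(e)))
  L <- chol(R + diag(1e-10, nrow(R)))
  Z <- matrix(rnorm(spec$n * nrow(R)), spec$n) %*% L
  U <- pnorm(Z)
  colnames(U) <- colnames(R)
  X <- sapply(.cohort_vars, function(v)
    qnorm(U[, v], spec$param_means[[v]], spec$param_sds[[v]]))
  X <- rbind(X)
  colnames(X) <- .cohort_vars
  # physical clipping
  X[, "pf"] <- pmin(pmax(X[, "pf"], 1e-3), 0.99)
  X[, "fa"] <- pmin(pmax(X[, "fa"], 0), 0.99)
  for (v in c("dslow", "md", "r2star", "alt", "ast", "ldh", "mda", "mpo", "sod"))
    X[, v] <- pmax(X[, v], 0.01 * abs(spec$param_means[[v]]) + 1e-12)
  X[, "dfast"] <- pmax(X[, "dfast"], 2 * X[, "dslow"], 1e-4)
  df <- as.data.frame(X)
  is <- vapply(.score_vars, function(v) {
    p <- spec$score_dist[[v]]
    br <- cumsum(p) / sum(p)
    as.integer(names(p))[findInterval(U[, v], c(0, utils::head(br, -1)),
                                      left.open = TRUE) ]
  }, integer(spec$n))
  is <- rbind(is)
  df$i_score <- is[, "i_score"]
  df$f_score <- is[, "f_score"]
  df$group <- spec$name
  df
}

#' Sample a two-group synthetic cohort
#'
#' Draws per-animal ground-truth parameters from a Gaussian copula:
#' correlated standard normals (Cholesky of the Pearson image of the
#' Spearman targets, `2*sin(pi*rho/6)`) are pushed through the Gaussian
#' marginal quantile functions; score variables use the discrete inverse
#' CDF of their score distribution. Physical clipping keeps PF in (0, 1),
#' diffusivities/rates positive and `dfast > dslow`.
#'
#' @param control,model [group_spec] objects.
#' @param seed integer seed governing all randomness.
#' @return data frame of class `"cohort_table"`: one row per animal with
#'   `id`, `group`, the 12 continuous variables and `i_score`, `f_score`.
#' @examples
#' coh <- sample_cohort(seed = 1)
#' aggregate(pf ~ group, coh, mean)
#' @export
sample_cohort <- function(control = default_group_spec("control"),
                          model = default_group_spec("model"),
                          seed = 1L) {
  a <- .sample_group(control, seed)
  b <- .sample_group(model, seed + 1000003L)
  out <- rbind(a, b)
  out <- cbind(id = sprintf("%s_%02d", out$group,
                            c(seq_len(nrow(a)), seq_len(nrow(b)))),
               out)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Noise model
#'
#' @param kind `"rician"` (magnitude images; the physically appropriate
#'   model), `"gaussian"`, or `"none"`.
#' @param snr signal-to-noise ratio at b = 0 / first echo.
#' @param seed integer seed for voxel parameter spread and noise draws.
#' @export
noise_model <- function(kind = c("rician", "gaussian", "none"), snr = 50,
                        seed = 1L) {
  kind <- match.arg(kind)
  if (kind != "none" && !(is.finite(snr) && snr > 0))
    stop("snr must be positive when noise kind is not 'none'")
  structure(list(kind = kind, snr = snr, seed = as.integer(seed)),
            class = "noise_model")
}

#' Phantom layout
#'
#' Voxel grid with a cylindrical liver mask on a set of slices and small
#' intrahepatic "vessels" (high-perfusion inclusions used to exercise ROI
#' exclusion). Vessel voxels are a subset of liver voxels; the liver is
#' present on at least 3 slices.
#'
#' @param grid_shape 3-D dimensions.
#' @param liver_slices slice indices carrying liver.
#' @param liver_radius liver disc radius (pixels).
#' @param vessel_centers list of in-plane centers of vessel discs.
#' @param vessel_radius vessel disc radius (pixels).
#' @export
phantom_layout <- function(grid_shape = c(20, 20, 5), liver_slices = 2:4,
                           liver_radius = 7,
                           vessel_centers = list(c(-3, -2), c(3, 2)),
                           vessel_radius = 1.2) {
  if (length(liver_slices) < 3L) stop("liver must cover at least 3 slices")
  cx <- (grid_shape[1] + 1) / 2; cy <- (grid_shape[2] + 1) / 2
  d2 <- outer((seq_len(grid_shape[1]) - cx)^2,
              (seq_len(grid_shape[2]) - cy)^2, `+`)
  liver <- vessel <- array(FALSE, grid_shape)
  disc <- d2 <= liver_radius^2
  vd <- Reduce(`|`, lapply(vessel_centers, function(ct)
    outer((seq_len(grid_shape[1]) - cx - ct[1])^2,
          (seq_len(grid_shape[2]) - cy - ct[2])^2, `+`) <= vessel_radius^2))
  for (z in liver_slices) { liver[, , z] <- disc; vessel[, , z] <- vd & disc }
  structure(list(grid_shape = grid_shape, liver_mask = liver,
                 vessel_mask = vessel, slice_count = grid_shape[3],
                 liver_slices = liver_slices),
            class = "phantom_layout")
}

#' @rdname phantom_layout
#' @param liver_mask,vessel_mask logical 3-D arrays with
#'   `vessel_mask` a subset of `liver_mask`.
#' @export
phantom_layout_from_masks <- function(liver_mask, vessel_mask = NULL) {
  if (is.null(vessel_mask)) vessel_mask <- array(FALSE, dim(liver_mask))
  if (any(vessel_mask & !liver_mask))
    stop("vessel mask must be a subset of the liver mask")
  sl <- which(apply(liver_mask, 3, any))
  if (length(sl) < 3L) stop("liver must cover at least 3 slices")
  structure(list(grid_shape = dim(liver_mask), liver_mask = liver_mask,
                 vessel_mask = vessel_mask, slice_count = dim(liver_mask)[3],
                 liver_slices = sl),
            class = "phantom_layout")
}

#' 4-D image series
#'
#' @param data 4-D numeric array (x, y, z, volume).
#' @param scheme the acquisition scheme the 4th dimension follows.
#' @param liver_mask,vessel_mask logical 3-D arrays.
#' @param voxel_dims voxel size in mm, stored as metadata.
#' @export
image_series <- function(data, scheme, liver_mask, vessel_mask = NULL,
                         voxel_dims = c(1.9, 1.9, 4.0)) {
  nvol <- switch(class(scheme)[1],
                 bvalue_scheme = length(scheme$b),
                 gradient_scheme = nrow(scheme$directions) + 1L,
                 echo_scheme = length(scheme$te),
                 stop("unknown scheme class"))
  if (length(dim(data)) != 4L || dim(data)[4] != nvol)
    stop("series length does not match the acquisition scheme")
  structure(list(data = data, scheme = scheme, liver_mask = liver_mask,
                 vessel_mask = vessel_mask, voxel_dims = voxel_dims),
            class = "image_series")
}

.add_noise <- function(S, sigma, kind) {
  if (kind == "none" || sigma == 0) return(S)
  n1 <- array(rnorm(length(S), 0, sigma), dim(S))
  if (kind == "gaussian") return(S + n1)
  n2 <- array(rnorm(length(S), 0, sigma), dim(S))
  sqrt((S + n1)^2 + n2^2)
}

#' Render the three MR series for one animal
#'
#' Evaluates the three forward models voxel by voxel. Liver voxels draw
#' their parameters from a narrow spread (default 5% coefficient of
#' variation) around the animal's ground truth; vessel voxels are given
#' high perfusion (PF >= 0.6, Dfast >= 3x the liver value) so the ROI
#' protocol's vessel exclusion has something to exclude. Background is
#' zero signal; Rician noise turns it into a Rayleigh floor. All
#' randomness (spread and noise) is governed by `noise$seed`, so rendering
#' is bit-reproducible.
#'
#' @param record one-row animal record (a [sample_cohort()] row or
#'   equivalent list) carrying the ground-truth parameters.
#' @param layout a [phantom_layout].
#' @param schemes list with elements `ivim`, `dti`, `bold`.
#' @param noise a [noise_model].
#' @param cv within-animal voxel coefficient of variation.
#' @param s0 mean liver b0 / first-echo signal (arbitrary units).
#' @return list of class `"animal_series"` with [image_series] elements
#'   `ivim`, `dti`, `bold`, plus `truth_maps` (voxelwise ground-truth
#'   parameter arrays) and the input `record`.
#' @export
render_animal <- function(record, layout,
                          schemes = list(ivim = bvalue_scheme(),
                                         dti = gradient_scheme(),
                                         bold = echo_scheme()),
                          noise = noise_model(), cv = 0.05, s0 = 100) {
  stopifnot(inherits(layout, "phantom_layout"))
  set.seed(noise$seed)
  dm <- layout$grid_shape
  liv <- which(layout$liver_mask)
  ves <- layout$vessel_mask[liv]
  V <- length(liv)
  jig <- function(mu, lo = -Inf, hi = Inf)
    pmin(pmax(mu * (1 + cv * rnorm(V)), lo), hi)
  pf <- jig(record$pf, 1e-3, 0.99)
  ds <- jig(record$dslow, 1e-6)
  df <- pmax(jig(record$dfast, 1e-4), 2 * ds)
  md <- jig(record$md, 1e-6)
  fa <- jig(record$fa, 0, 0.99)
  r2 <- jig(record$r2star, 1)
  s0v <- jig(s0, 1)
  if (any(ves)) {
    pf[ves] <- pmin(pmax(0.75 * (1 + cv * rnorm(sum(ves))), 0.6), 0.95)
    df[ves] <- pmax(3.5 * record$dfast * (1 + cv * rnorm(sum(ves))),
                    3 * record$dfast)
  }
  sigma <- if (noise$kind == "none") 0 else s0 / noise$snr

  # IVIM series
  b <- schemes$ivim$b
  Sv <- s0v * (pf * exp(-outer(df, b)) + (1 - pf) * exp(-outer(ds, b)))
  ivim <- array(0, c(dm, length(b)))
  for (k in seq_along(b)) { vol <- array(0, dm); vol[liv] <- Sv[, k]
                            ivim[, , , k] <- vol }
  ivim <- .add_noise(ivim, sigma, noise$kind)

  # DTI series: per-voxel prolate tensor, random principal axis
  u <- matrix(rnorm(3 * V), V, 3); u <- u / sqrt(rowSums(u^2))
  delta <- fa * sqrt(3 / (9 - 6 * fa^2))
  l1 <- md * (1 + 2 * delta); l2 <- md * (1 - delta)
  E <- cbind(l2 + (l1 - l2) * u[, 1]^2,
             l2 + (l1 - l2) * u[, 2]^2,
             l2 + (l1 - l2) * u[, 3]^2,
             (l1 - l2) * u[, 1] * u[, 2],
             (l1 - l2) * u[, 1] * u[, 3],
             (l1 - l2) * u[, 2] * u[, 3])
  adc <- E %*% t(dti_design(schemes$dti$directions))     # V x 12
  Sd <- cbind(s0v * exp(-schemes$dti$b_low * rowMeans(adc)),
              s0v * exp(-schemes$dti$b_high * adc))
  dti <- array(0, c(dm, ncol(Sd)))
  for (k in seq_len(ncol(Sd))) { vol <- array(0, dm); vol[liv] <- Sd[, k]
                                 dti[, , , k] <- vol }
  dti <- .add_noise(dti, sigma, noise$kind)

  # multi-echo gradient-echo series
  te <- schemes$bold$te / 1000
  Sb <- s0v * exp(-outer(r2, te))
  bold <- array(0, c(dm, length(te)))
  for (k in seq_along(te)) { vol <- array(0, dm); vol[liv] <- Sb[, k]
                             bold[, , , k] <- vol }
  bold <- .add_noise(bold, sigma, noise$kind)

  mk <- function(v) { a <- array(NA_real_, dm); a[liv] <- v; a }
  structure(list(
    ivim = image_series(ivim, schemes$ivim, layout$liver_mask,
                        layout$vessel_mask),
    dti = image_series(dti, schemes$dti, layout$liver_mask,
                       layout$vessel_mask, voxel_dims = c(1.4, 1.4, 4.0)),
    bold = image_series(bold, schemes$bold, layout$liver_mask,
                        layout$vessel_mask, voxel_dims = c(2.0, 1.6, 4.0)),
    truth_maps = list(dslow = mk(ds), dfast = mk(df), pf = mk(pf),
                      md = mk(md), fa = mk(fa), r2star = mk(r2)),
    record = record, layout = layout, noise = noise),
    class = "animal_series")
}
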