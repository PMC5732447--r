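#' Acquisition schemes
#'
#' Constructors and defaults for the three acquisition protocols used
#' throughout the package: an 11-b-value diffusion series for IVIM, a
#' 13-volume (1 x b=0 + 12 directions at b=500 s/mm^2) diffusion-tensor
#' series, and a 9-echo gradient-echo series for R2* relaxometry.
#'
#' @param b numeric vector of b-values in s/mm^2; must start at 0 and be
#'   strictly increasing.
#' @return `bvalue_scheme()` returns an object of class `"bvalue_scheme"`.
#' @examples
#' bvalue_scheme()          # the default 11-b-value protocol
#' gradient_scheme()        # default 12-direction tensor protocol
#' echo_scheme()            # default 9-echo protocol
#' @export
bvalue_scheme <- function(b = c(0, 20, 40, 60, 80, 100, 150, 200, 400, 600, 800)) {
  b <- as.numeric(b)
  if (length(b) < 4L) stop("need at least 4 b-values")
  if (b[1] != 0) stop("first b-value must be 0")
  if (any(diff(b) <= 0)) stop("b-values must be strictly increasing")
  structure(list(b = b), class = "bvalue_scheme")
}

# Electrostatic-repulsion 12-direction set (antipodally symmetrized energy,
# frozen after a one-off optimization; design matrix rank 6, min separation
# 38.9 degrees). Stored row-wise as unit vectors.
.dti12 <- matrix(c(
  -0.37056384, -0.03776384,  0.92803897,
  -0.28766227,  0.64101753,  0.71158059,
  -0.22819370,  0.77216303, -0.59303616,
  -0.17143549,  0.98100191,  0.09080269,
   0.28511219, -0.15068672,  0.94657517,
   0.44588250,  0.51468259,  0.73231866,
   0.48424002,  0.86807629,  0.10933963,
   0.50535112,  0.64582874, -0.57229842,
   0.77302477, -0.63373771, -0.02844693,
   0.83283839, -0.19685860,  0.51732670,
   0.87778896, -0.09775615, -0.46896725,
   0.93760186,  0.33912177,  0.07680607), ncol = 3, byrow = TRUE)

#' @rdname bvalue_scheme
#' @param directions numeric matrix, one unit gradient direction per row.
#' @param b_low,b_high the two diffusion weightings (s/mm^2).
#' @export
gradient_scheme <- function(directions = .dti12, b_low = 0, b_high = 500) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("directions must be an n x 3 matrix")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("gradient directions must be unit-norm to 1e-6")
  X <- dti_design(directions)
  if (qr(X)$rank < 6L)
    stop("direction set does not span the tensor space (design rank < 6)")
  structure(list(directions = directions, b_low = b_low, b_high = b_high),
            class = "gradient_scheme")
}

#' @rdname bvalue_scheme
#' @param te echo times in ms; strictly increasing, at least 3.
#' @param n_echo number of echoes when `te` is built from endpoints.
#' @param te_first,te_last first/last echo time (ms) for the default
#'   evenly spaced train.
#' @export
echo_scheme <- function(te = NULL, n_echo = 9, te_first = 2.57, te_last = 24.25) {
  if (is.null(te)) te <- seq(te_first, te_last, length.out = n_echo)
  te <- as.numeric(te)
  if (length(te) < 3L) stop("need at least 3 echoes for a stable fit")
  if (any(diff(te) <= 0)) stop("echo times must be strictly increasing")
  structure(list(te = te), class = "echo_scheme")
}

# 6-column tensor design rows [gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz]
dti_design <- function(directions) {
  g <- as.matrix(directions)
  cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
        2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}
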