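#' @importFrom stats pnorm pt qf pf t.test cor.test wilcox.test median var
NULL

.stats_result <- function(test, statistic, p_value, n1 = NA, n2 = NA,
                          estimate = NA, z = NA, df = NA) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), n1 = n1, n2 = n2,
                 estimate = unname(estimate), z = unname(z), df = df),
            class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g\n", x$test, x$statistic,
              if (!is.na(x$z)) sprintf(" (Z = %.4g)", x$z) else "",
              x$p_value))
  invisible(x)
}

#' Pooled-variance two-sample t test
#'
#' Independent-sample t with pooled variance, `df = n1 + n2 - 2`,
#' two-sided p. Sign convention: the statistic carries the sign of
#' `mean(a) - mean(b)` with `a` the group listed first.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return a `stats_result` with fields `statistic`, `df`, `p_value`.
#' @export
independent_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b))
      return(.stats_result("t", 0, 1, length(a), length(b),
                           df = length(a) + length(b) - 2))
    stop("zero pooled variance with unequal means")
  }
  tt <- t.test(a, b, var.equal = TRUE)
  .stats_result("t", tt$statistic, tt$p.value, length(a), length(b),
                estimate = mean(a) - mean(b), df = unname(tt$parameter))
}

#' Pooled t from group summaries
#'
#' Recomputes the pooled-variance two-sample t statistic from printed
#' summary statistics (mean, SD, n per group); equals [independent_t()]
#' on any raw data having exactly those summaries.
#'
#' @param m1,s1,n1 mean, SD and size of the first group.
#' @param m2,s2,n2 mean, SD and size of the second group.
#' @export
t_from_summaries <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tv <- if (se == 0) { if (m1 == m2) 0 else stop("zero pooled variance") }
        else (m1 - m2) / se
  df <- n1 + n2 - 2
  .stats_result("t", tv, 2 * pt(-abs(tv), df), n1, n2,
                estimate = m1 - m2, df = df)
}

# U = #{(i,j): a_i > b_j} + 0.5 #{a_i == b_j}
.u_stat <- function(a, b) {
  sum(outer(a, b, `>`)) + 0.5 * sum(outer(a, b, `==`))
}

#' Mann-Whitney U test
#'
#' Reports the U statistic for the first group, the (uncorrected) normal
#' approximation Z with tie correction — the quantity printed as "Z" by
#' mainstream statistics packages — and a two-sided p value. `exact = TRUE`
#' (default for n1 + n2 <= 16 without forcing) enumerates all group
#' assignments of the pooled sample and computes the permutation p
#' directly, handling ties; otherwise the normal approximation with
#' continuity correction is used.
#'
#' @param a,b numeric vectors.
#' @param exact force (`TRUE`)/suppress (`FALSE`) exact enumeration;
#'   default `NULL` enumerates when `n1 + n2 <= 16`.
#' @param continuity apply the 0.5 continuity correction in the
#'   approximate p (the reported Z is always uncorrected).
#' @return a `stats_result` with `statistic` = U, `z`, `p_value`.
#' @export
mann_whitney <- function(a, b, exact = NULL, continuity = TRUE) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  u <- .u_stat(a, b)
  pooled <- c(a, b)
  # tie-corrected normal approximation
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  varu <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (varu > 0) (u - mu) / sqrt(varu) else 0
  if (is.null(exact)) exact <- n <= 16
  if (varu == 0) {                       # all values identical
    p <- 1
  } else if (exact) {
    idx <- utils::combn(n, n1)
    us <- apply(idx, 2, function(i) .u_stat(pooled[i], pooled[-i]))
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
  } else {
    cc <- if (continuity) 0.5 * sign(u - mu) else 0
    zp <- (u - mu - cc) / sqrt(varu)
    p <- 2 * pnorm(-abs(zp))
  }
  .stats_result("mann_whitney", u, p, n1, n2, z = z)
}

#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Absolute-agreement, single-measure intraclass correlation from the
#' two-way random-effects model: subjects and raters both random, computed
#' from the two-way ANOVA mean squares
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The 95% confidence interval uses the F-based approximation with
#' Satterthwaite degrees of freedom. `model = "consistency"` gives
#' ICC(3,1), which ignores systematic rater offsets.
#'
#' @param obs1,obs2 numeric vectors: the same subjects measured by two
#'   observers (length >= 3).
#' @param model `"agreement"` (ICC(2,1), default) or `"consistency"`
#'   (ICC(3,1)).
#' @param conf_level confidence level.
#' @return object of class `"icc_result"`: `icc`, `ci_low`, `ci_high`,
#'   `model`, `n`, `degenerate`.
#' @export
icc_two_way <- function(obs1, obs2, model = c("agreement", "consistency"),
                        conf_level = 0.95) {
  model <- match.arg(model)
  stopifnot(length(obs1) == length(obs2), length(obs1) >= 3)
  X <- cbind(obs1, obs2)
  n <- nrow(X); k <- ncol(X)
  gm <- mean(X)
  rm_ <- rowMeans(X); cm <- colMeans(X)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  mse <- sum((X - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + gm)^2) / ((n - 1) * (k - 1))
  degenerate <- msr <= mse
  alpha <- 1 - conf_level
  if (model == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse == 0) return(structure(list(icc = as.numeric(msr > 0), ci_low = NA,
                                        ci_high = NA, model = model, n = n,
                                        degenerate = degenerate),
                                   class = "icc_result"))
    f <- msr / mse
    f1 <- qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    f2 <- qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (f / f1 - 1) / (f / f1 + k - 1)
    hi <- (f * f2 - 1) / (f * f2 + k - 1)
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    if (mse == 0 && msc == 0) return(structure(
      list(icc = as.numeric(msr > 0), ci_low = NA, ci_high = NA,
           model = model, n = n, degenerate = degenerate),
      class = "icc_result"))
    a <- k * icc / (n * (1 - icc))
    b2 <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b2 * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b2 * mse)^2 / ((n - 1) * (k - 1)))
    f1 <- qf(1 - alpha / 2, n - 1, v)
    f2 <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  }
  structure(list(icc = icc, ci_low = min(lo, icc), ci_high = max(hi, icc),
                 model = model, n = n, degenerate = degenerate),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s,1) = %.3f (95%% CI %.3f-%.3f), n = %d%s\n",
              if (x$model == "agreement") "2" else "3",
              x$icc, x$ci_low, x$ci_high, x$n,
              if (x$degenerate) " [degenerate: no between-subject variance]"
              else ""))
  invisible(x)
}

#' Pearson or Spearman correlation
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"spearman"` (default, average-rank ties) or
#'   `"pearson"`.
#' @return a `stats_result`; `estimate` holds r or rho.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  .stats_result(method, ct$statistic, ct$p.value, n1 = length(x),
                estimate = ct$estimate)
}

#' Percent change of the model group against the control mean
#'
#' For each model-group animal, the percent change relative to the
#' control-group mean: `100 * (mean(control) - x) / mean(control)` when
#' `direction = "decrease"`, sign-flipped for `"increase"`. Returns the
#' mean and SD over model animals (the convention behind "decreased
#' 25.01 +/- 16.69%"-style summaries).
#'
#' @param control,model numeric vectors.
#' @param direction `"decrease"` or `"increase"`.
#' @return list `mean`, `sd`, `values`, `direction`.
#' @export
percent_change <- function(control, model,
                           direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  stopifnot(length(control) >= 1, length(model) >= 1)
  mc <- mean(control)
  if (mc == 0) stop("control mean is zero; percent change undefined")
  v <- 100 * (mc - model) / mc
  if (direction == "increase") v <- -v
  list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
       values = v, direction = direction)
}
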