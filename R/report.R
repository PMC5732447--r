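.mr_vars <- c("dslow", "dfast", "pf", "md", "fa", "r2star")
.ref_vars <- c("alt", "ast", "ldh", "mda", "mpo", "sod", "i_score", "f_score")

#' Default test routing
#'
#' Which two-group test each variable gets in [build_report()]: pooled t
#' for the variables customarily summarized as mean +/- SD, Mann-Whitney U
#' for the skewed enzymes and the ordinal scores.
#'
#' @export
default_routing <- function() {
  c(dslow = "t", dfast = "t", pf = "t", md = "t", fa = "t", r2star = "t",
    mda = "t", mpo = "t", sod = "t",
    alt = "mann_whitney", ast = "mann_whitney", ldh = "mann_whitney",
    i_score = "mann_whitney", f_score = "mann_whitney")
}

#' Cohort statistics report
#'
#' Reproduces the study's statistical battery on a cohort table: per-variable
#' group comparison (pooled t or Mann-Whitney U per the routing), the
#' Spearman (or Pearson) correlation matrix of the six MR parameters
#' against the eight reference variables, percent-change summaries for the
#' perfusion-sensitive parameters, and — when two-observer measurements are
#' supplied — an interobserver ICC(2,1) table.
#'
#' @param cohort a `cohort_table` (or any data frame with the same
#'   columns, first group listed first).
#' @param routing named character vector mapping variables to `"t"` or
#'   `"mann_whitney"`; see [default_routing()].
#' @param observers optional list of two data frames (`obs1`, `obs2`) of
#'   per-animal MR values, same rows, columns among the MR parameters.
#' @param cor_method `"spearman"` (default) or `"pearson"`.
#' @return list of class `"stats_report"` with data frames
#'   `group_comparison`, `correlations`, `percent_change` and optionally
#'   `icc`.
#' @export
build_report <- function(cohort, routing = default_routing(),
                         observers = NULL,
                         cor_method = c("spearman", "pearson")) {
  cor_method <- match.arg(cor_method)
  grp <- unique(as.character(cohort$group))
  two_groups <- length(grp) >= 2
  vars <- intersect(names(routing), names(cohort))
  if (length(miss <- setdiff(names(routing), names(cohort))))
    warning("variables missing from cohort, omitted: ",
            paste(miss, collapse = ", "))
  gc <- NULL
  if (two_groups) {
    a_all <- cohort[cohort$group == grp[1], ]
    b_all <- cohort[cohort$group == grp[2], ]
    gc <- do.call(rbind, lapply(vars, function(v) {
      a <- a_all[[v]]; b <- b_all[[v]]
      if (routing[[v]] == "t") {
        r <- independent_t(a, b)
        stat <- r$statistic; z <- NA_real_
      } else {
        r <- mann_whitney(a, b)
        stat <- r$statistic; z <- r$z
      }
      data.frame(variable = v, test = routing[[v]],
                 mean_1 = mean(a), sd_1 = sd(a),
                 median_1 = median(a),
                 mean_2 = mean(b), sd_2 = sd(b),
                 median_2 = median(b),
                 statistic = stat, z = z, p_value = r$p_value)
    }))
    names(gc) <- sub("_1$", paste0("_", grp[1]), names(gc))
    names(gc) <- sub("_2$", paste0("_", grp[2]), names(gc))
  }
  mr <- intersect(.mr_vars, names(cohort))
  rf <- intersect(.ref_vars, names(cohort))
  cors <- do.call(rbind, lapply(mr, function(u) do.call(rbind, lapply(rf,
    function(v) {
      r <- tryCatch(correlate(cohort[[u]], cohort[[v]], method = cor_method),
                    error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(mr = u, reference = v, estimate = r$estimate,
                 p_value = r$p_value, method = cor_method)
    }))))
  pc <- NULL
  if (two_groups) {
    pc <- do.call(rbind, lapply(
      list(c("dfast", "decrease"), c("pf", "decrease"),
           c("r2star", "increase")),
      function(x) {
        p <- percent_change(a_all[[x[1]]], b_all[[x[1]]], direction = x[2])
        data.frame(variable = x[1], direction = x[2],
                   mean = p$mean, sd = p$sd)
      }))
  }
  out <- list(group_comparison = gc, correlations = cors,
              percent_change = pc, groups = grp)
  if (!is.null(observers)) {
    common <- intersect(intersect(names(observers$obs1), names(observers$obs2)),
                        .mr_vars)
    out$icc <- do.call(rbind, lapply(common, function(v) {
      r <- icc_two_way(observers$obs1[[v]], observers$obs2[[v]])
      data.frame(variable = v, icc = r$icc, ci_low = r$ci_low,
                 ci_high = r$ci_high, n = r$n)
    }))
  }
  structure(out, class = "stats_report")
}

#' @export
print.stats_report <- function(x, digits = 3, ...) {
  if (!is.null(x$group_comparison)) {
    cat("Group comparison (", paste(x$groups, collapse = " vs "), "):\n",
        sep = "")
    print(format(x$group_comparison, digits = digits), row.names = FALSE)
  }
  if (!is.null(x$percent_change)) {
    cat("\nPercent change of model group vs control mean:\n")
    print(format(x$percent_change, digits = digits), row.names = FALSE)
  }
  if (!is.null(x$icc)) {
    cat("\nInterobserver ICC(2,1):\n")
    print(format(x$icc, digits = digits), row.names = FALSE)
  }
  cat("\nCorrelations (", x$correlations$method[1], ", first rows):\n",
      sep = "")
  print(format(utils::head(x$correlations, 8), digits = digits),
        row.names = FALSE)
  invisible(x)
}
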