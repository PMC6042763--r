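#' Standard weight of a Lake Trout from total length
#'
#' Species-wide expected weight at length from the published log-log
#' standard-weight equation for Lake Trout,
#' log10(Ws) = -5.681 + 3.2462 * log10(TL).
#'
#' @param tl_mm total length, mm (> 0)
#' @return standard weight, g
#' @export
standard_weight <- function(tl_mm) {
  if (any(tl_mm <= 0)) stop("standard_weight: TL must be > 0", call. = FALSE)
  10^(-5.681 + 3.2462 * log10(tl_mm))
}

#' Relative weight condition index
#'
#' Wr = 100 * W / Ws: measured weight as a percentage of the species
#' standard weight at that length. Values near 100 indicate typical
#' plumpness; values well below 100 suggest poor condition.
#'
#' @param w measured weight, g (> 0)
#' @param ws standard weight, g (> 0)
#' @return relative weight (dimensionless, ~100 scale)
#' @export
relative_weight <- function(w, ws) {
  if (any(w <= 0) || any(ws <= 0)) {
    stop("relative_weight: weights must be > 0", call. = FALSE)
  }
  100 * w / ws
}

#' Welch two-sample t test
#'
#' Unequal-variance two-sample t test with the Welch-Satterthwaite
#' (real-valued) degrees of freedom, used to check that mean condition is
#' comparable between ecotypes in unstocked lakes.
#'
#' @param a,b numeric vectors (each >= 2 values with positive variance)
#' @return list of class `welch_test`: statistic (t), df, p.value
#' @export
welch_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("welch_test: each group needs >= 2 values", call. = FALSE)
  }
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("welch_test: degenerate zero-variance group", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p.value = tt$p.value),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t-test: t(%.1f) = %.3f, p = %.3g\n",
              x$df, x$statistic, x$p.value))
  invisible(x)
}

#' Simple regression of relative weight on a predictor
#'
#' Ordinary least squares of Wr on a single predictor - total length, age,
#' or percent local genetic assignment (0-100 scale) - reporting the slope
#' and intercept, the two-sided p-value of the slope t test, the adjusted
#' R-squared 1 - (1 - R2)(n - 1)/(n - 2), and n. An optional logical
#' `subset` restricts the fit, e.g. to hybrid-classified fish only.
#'
#' The ancestry predictor is expressed in percent, not proportion: the
#' slope is then in Wr units per percentage point of local assignment.
#'
#' @param predictor numeric predictor
#' @param wr relative weight values
#' @param subset optional logical vector selecting observations
#' @return object of class `wr_regression`: slope, intercept, p, adj_r2, n,
#'   and the underlying `lm` fit
#' @export
regress_wr <- function(predictor, wr, subset = NULL) {
  if (!is.null(subset)) {
    predictor <- predictor[subset]
    wr <- wr[subset]
  }
  n <- length(wr)
  if (n < 3) stop("regress_wr: need n >= 3 after subsetting", call. = FALSE)
  if (stats::sd(predictor) == 0) {
    stop("regress_wr: constant predictor (rank-deficient design)",
         call. = FALSE)
  }
  fit <- stats::lm(wr ~ predictor)
  # summary.lm warns when the data sit exactly on a line
  sm <- suppressWarnings(summary(fit))
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    p = sm$coefficients[2, "Pr(>|t|)"],
    adj_r2 = sm$adj.r.squared,
    n = n,
    fit = fit
  ), class = "wr_regression")
}

#' @export
print.wr_regression <- function(x, ...) {
  cat(sprintf("Wr regression: y = %.3gx + %.3g, p = %.3g, adjR2 = %.2f, n = %d\n",
              x$slope, x$intercept, x$p, x$adj_r2, x$n))
  invisible(x)
}

#' @export
#' @param object a `wr_regression`
#' @param parm,level passed to [stats::confint()]
#' @rdname regress_wr
confint.wr_regression <- function(object, parm, level = 0.95, ...) {
  ci <- stats::confint(object$fit, level = level)
  rownames(ci) <- c("intercept", "slope")
  ci
}
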