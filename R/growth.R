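#' Fit the length-otolith power regression
#'
#' Fits L = u * S^v by ordinary least squares on the log-transformed model
#' ln(L) = v ln(S) + ln(u), the standard calibration for otolith
#' back-calculation. R-squared and residual SD are reported on the log
#' scale.
#'
#' @param S otolith radii at capture, um (> 0)
#' @param L total lengths at capture, mm (> 0)
#' @return object of class `power_fit`: u, v, r2, n, sigma_log and the
#'   underlying `lm` fit
#' @export
fit_power_regression <- function(S, L) {
  if (length(S) != length(L)) {
    stop("fit_power_regression: S and L must have equal length", call. = FALSE)
  }
  if (length(S) < 3) {
    stop("fit_power_regression: need at least 3 pairs", call. = FALSE)
  }
  if (any(S <= 0) || any(L <= 0)) {
    stop("fit_power_regression: all values must be positive", call. = FALSE)
  }
  fit <- stats::lm(log(L) ~ log(S))
  # summary.lm warns on exactly collinear (noise-free) calibration data
  sm <- suppressWarnings(summary(fit))
  structure(list(
    u = unname(exp(stats::coef(fit)[1])),
    v = unname(stats::coef(fit)[2]),
    r2 = sm$r.squared,
    n = length(S),
    sigma_log = sm$sigma,
    fit = fit
  ), class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat(sprintf("Length-otolith power regression: L = %.4g * S^%.4g  (n = %d, log-scale R2 = %.3f)\n",
              x$u, x$v, x$n, x$r2))
  invisible(x)
}

#' @export
predict.power_fit <- function(object, S, ...) object$u * S^object$v

#' Test homogeneity of the log-log regression slopes between groups
#'
#' ANCOVA-style F test of the group x ln(S) interaction in the pooled model
#' ln(L) ~ ln(S) * group, used to decide whether ecotype-specific
#' back-calculation regressions are required. With two groups the F
#' statistic on (1, n - 4) df is the square of the interaction t statistic.
#'
#' @param S otolith radii, um
#' @param L total lengths, mm
#' @param group grouping factor with two levels (e.g. ecotype)
#' @return list of class `slope_test`: statistic (F), df (length 2), p.value
#' @export
compare_slopes <- function(S, L, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) != 2) {
    stop("compare_slopes: exactly two non-empty groups required", call. = FALSE)
  }
  if (any(table(group) < 3)) {
    stop("compare_slopes: each group needs at least 3 pairs", call. = FALSE)
  }
  fit <- stats::lm(log(L) ~ log(S) * group)
  ct <- summary(fit)$coefficients
  tstat <- ct[4, "t value"]
  df2 <- stats::df.residual(fit)
  Fstat <- tstat^2
  structure(list(statistic = unname(Fstat), df = c(1, df2),
                 p.value = unname(stats::pf(Fstat, 1, df2, lower.tail = FALSE)),
                 fit = fit),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf("Slope homogeneity: F(%d, %d) = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$statistic, x$p.value))
  invisible(x)
}

#' Back-calculate length-at-age under the body proportional hypothesis
#'
#' L_i = (S_i / S)^v * L: the fish's length at annulus i scales its capture
#' length by the annulus-to-capture radius ratio raised to the regression
#' exponent v.
#'
#' @param L total length at capture, mm
#' @param S otolith radius at capture, um
#' @param S_i annulus radii, um (each <= S)
#' @param v exponent of the length-otolith power regression
#' @return back-calculated lengths, mm, one per annulus
#' @export
back_calculate <- function(L, S, S_i, v) {
  if (L <= 0 || S <= 0 || any(S_i <= 0)) {
    stop("back_calculate: lengths and radii must be positive", call. = FALSE)
  }
  if (any(S_i > S)) {
    stop(structure(class = c("troutgrowth_monotonicity", "error", "condition"),
                   list(message = "back_calculate: annulus radius exceeds capture radius",
                        call = NULL)))
  }
  (S_i / S)^v * L
}

## Back-calculate a whole cohort: ecotype-specific power fits from the
## capture rows, BPH per fish; fish whose annuli exceed the capture radius
## are excluded and reported.
#' Back-calculate length-at-age for every fish in a cohort
#'
#' Fits the length-otolith power regression separately per ecotype from the
#' capture radii and capture lengths, then applies the body proportional
#' hypothesis to every annulus of every fish. Fish violating radius
#' monotonicity (an annulus larger than the capture radius) are excluded
#' and listed in the `excluded` attribute.
#'
#' @param fish per-fish table with fish_id, ecotype, tl_mm
#' @param otoliths long annulus table with fish_id, annulus_index,
#'   radius_um, is_capture_radius
#' @return data.frame (fish_id, age, length_mm) with attributes
#'   `power_fits` (named list per ecotype) and `excluded` (fish ids)
#' @export
back_calculate_cohort <- function(fish, otoliths) {
  cap <- otoliths[otoliths$is_capture_radius, c("fish_id", "radius_um")]
  names(cap)[2] <- "capture_radius_um"
  d <- merge(fish, cap, by = "fish_id")
  pfits <- lapply(split(d, d$ecotype), function(g) {
    fit_power_regression(g$capture_radius_um, g$tl_mm)
  })
  ann <- otoliths[!otoliths$is_capture_radius, ]
  excluded <- character(0)
  res <- lapply(seq_len(nrow(d)), function(i) {
    row <- d[i, ]
    a <- ann[ann$fish_id == row$fish_id, ]
    a <- a[order(a$annulus_index), ]
    if (nrow(a) == 0) return(NULL)
    v <- pfits[[row$ecotype]]$v
    L_i <- tryCatch(
      back_calculate(row$tl_mm, row$capture_radius_um, a$radius_um, v),
      troutgrowth_monotonicity = function(e) NULL)
    if (is.null(L_i)) {
      excluded <<- c(excluded, row$fish_id)
      return(NULL)
    }
    data.frame(fish_id = row$fish_id, age = a$annulus_index,
               length_mm = L_i, stringsAsFactors = FALSE)
  })
  if (length(excluded) > 0) {
    message("back_calculate_cohort: excluded ", length(excluded),
            " fish with non-monotonic radii: ",
            paste(excluded, collapse = ", "))
  }
  out <- do.call(rbind, res)
  attr(out, "power_fits") <- pfits
  attr(out, "excluded") <- excluded
  out
}

#' Ford-Walford starting values for the Von Bertalanffy model
#'
#' Regresses mean length at age t+1 on mean length at age t over consecutive
#' ages; the slope b and intercept a give K = -ln(b) and
#' L_inf = a / (1 - b), and t0 is the average of
#' t + ln(1 - L_t / L_inf) / K over ages with L_t < L_inf. When the slope
#' is outside (0, 1) the curve cannot be inverted and conservative fallback
#' starts are returned with `fallback = TRUE`.
#'
#' @param age ages, yr (repeated ages allowed; means are taken per age)
#' @param length_mm lengths at age, mm
#' @return list with linf, k, t0, fallback
#' @export
ford_walford_start <- function(age, length_mm) {
  ml <- tapply(length_mm, age, mean)
  ages <- as.numeric(names(ml))
  o <- order(ages)
  ages <- ages[o]; ml <- as.numeric(ml)[o]
  idx <- which(diff(ages) == 1)
  fallback <- list(linf = 1.1 * max(length_mm), k = 0.2, t0 = 0,
                   fallback = TRUE)
  if (length(idx) < 2) return(fallback)
  x <- ml[idx]; y <- ml[idx + 1]
  if (stats::sd(x) == 0) return(fallback)
  fit <- stats::lm(y ~ x)
  b <- unname(stats::coef(fit)[2]); a <- unname(stats::coef(fit)[1])
  if (!is.finite(b) || b >= 1 || b <= 0) return(fallback)
  k <- -log(b)
  linf <- a / (1 - b)
  if (!is.finite(linf) || linf <= 0) return(fallback)
  usable <- ml < linf
  t0 <- mean(ages[usable] + log(1 - ml[usable] / linf) / k)
  list(linf = linf, k = k, t0 = t0, fallback = FALSE)
}

#' Fit a Von Bertalanffy growth model
#'
#' Nonlinear least squares fit of L_t = L_inf * (1 - exp(-K (t - t0))) to
#' length-at-age observations, for one fish or for a pooled population
#' series. Starting values default to the Ford-Walford method; optimization
#' is Levenberg-Marquardt least squares (up to `maxiter` iterations) with
#' one restart from the conservative fallback starts on failure. Bootstrap
#' standard errors can be requested directly via `boot_reps`, or added later
#' with [bootstrap_se()].
#'
#' @param age ages, yr
#' @param length_mm lengths at age, mm
#' @param starts optional list with linf, k, t0; default Ford-Walford
#' @param boot_reps nonparametric bootstrap replicates for the SEs
#'   (0 = asymptotic SEs only)
#' @param seed optional seed for the bootstrap
#' @param maxiter optimizer iteration cap
#' @return object of class `vbgm_fit` with coefficients (linf, k, t0),
#'   asymptotic and (if requested) bootstrap SEs, omega = L_inf * K,
#'   convergence and retention flags, data, fitted values and residuals
#' @seealso [bootstrap_se()], [filter_fits()], [omega()]
#' @export
fit_vbgm <- function(age, length_mm, starts = NULL, boot_reps = 0,
                     seed = NULL, maxiter = 500) {
  if (length(age) != length(length_mm)) {
    stop("fit_vbgm: age and length_mm must have equal length", call. = FALSE)
  }
  if (length(unique(age)) < 4) {
    stop("fit_vbgm: need observations at >= 4 distinct ages", call. = FALSE)
  }
  d <- data.frame(age = age, length_mm = length_mm)
  if (is.null(starts)) starts <- ford_walford_start(age, length_mm)
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter)

  try_fit <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(length_mm ~ linf * (1 - exp(-k * (age - t0))),
                        data = d,
                        start = list(linf = st$linf, k = st$k, t0 = st$t0),
                        control = ctrl),
      error = function(e) NULL)
  }
  fit <- try_fit(starts)
  if (is.null(fit) || any(!is.finite(stats::coef(fit))) ||
      stats::coef(fit)[["k"]] <= 0 || stats::coef(fit)[["linf"]] <= 0) {
    fit <- try_fit(list(linf = 1.1 * max(length_mm), k = 0.2, t0 = 0))
  }

  obj <- structure(list(
    coefficients = c(linf = NA_real_, k = NA_real_, t0 = NA_real_),
    se = c(linf = NA_real_, k = NA_real_, t0 = NA_real_),
    boot = NULL, omega = NA_real_,
    n_points = nrow(d), converged = FALSE, retained = NA,
    data = d, fitted = NULL, residuals = NULL, starts = starts,
    fit = fit, call = match.call()
  ), class = "vbgm_fit")

  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    if (all(is.finite(cf)) && cf[["k"]] > 0 && cf[["linf"]] > 0) {
      sm <- summary(fit)
      obj$coefficients <- c(linf = cf[["linf"]], k = cf[["k"]], t0 = cf[["t0"]])
      obj$se <- stats::setNames(sm$coefficients[, "Std. Error"],
                                c("linf", "k", "t0"))
      obj$omega <- omega(cf[["linf"]], cf[["k"]])
      obj$converged <- TRUE
      obj$fitted <- as.numeric(stats::fitted(fit))
      obj$residuals <- as.numeric(stats::residuals(fit))
    }
  }
  if (boot_reps > 0 && obj$converged) {
    obj <- bootstrap_se(obj, reps = boot_reps, seed = seed)
  }
  obj
}

#' Bootstrap standard errors for a Von Bertalanffy fit
#'
#' Nonparametric case resampling: the (age, length) observations are
#' resampled with replacement, the model is refit per replicate starting
#' from the original point estimates, and the SE of each parameter is the
#' SD of its estimates over converged replicates. Replicates that fail to
#' converge are counted; if more than half fail the SEs are flagged
#' unreliable.
#'
#' @param object a converged `vbgm_fit`
#' @param reps bootstrap replicates (default 999)
#' @param seed optional integer seed; fixing it makes the SEs reproducible
#' @return the `vbgm_fit` with `$boot` (reps, se, n_failed, reliable) set
#'   and `$se` replaced by the bootstrap SEs
#' @export
bootstrap_se <- function(object, reps = 999, seed = NULL) {
  stopifnot(inherits(object, "vbgm_fit"))
  if (!object$converged) {
    stop("bootstrap_se: fit did not converge", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  st <- as.list(object$coefficients)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  n <- nrow(d)
  est <- matrix(NA_real_, nrow = reps, ncol = 3,
                dimnames = list(NULL, c("linf", "k", "t0")))
  for (r in seq_len(reps)) {
    db <- d[sample.int(n, n, replace = TRUE), ]
    fit <- tryCatch(
      minpack.lm::nlsLM(length_mm ~ linf * (1 - exp(-k * (age - t0))),
                        data = db, start = st, control = ctrl),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      if (all(is.finite(cf)) && cf[["k"]] > 0) est[r, ] <- cf
    }
  }
  ok <- stats::complete.cases(est)
  n_failed <- sum(!ok)
  se <- apply(est[ok, , drop = FALSE], 2, stats::sd)
  object$boot <- list(reps = reps, se = se, n_failed = n_failed,
                      reliable = n_failed <= reps / 2)
  if (!object$boot$reliable) {
    warning("bootstrap_se: more than half of the replicates failed; SEs unreliable")
  }
  object$se <- se
  object
}

#' Early-life growth rate omega
#'
#' omega = L_inf * K, the slope of the Von Bertalanffy curve at t = t0, in
#' mm/yr. It is directly interpretable as the growth rate early in life and
#' statistically better behaved than K alone.
#'
#' @param linf asymptotic length, mm
#' @param k growth coefficient, 1/yr
#' @return growth rate, mm/yr
#' @export
omega <- function(linf, k) linf * k

#' Tabulate a set of Von Bertalanffy fits
#'
#' @param fits list of `vbgm_fit` objects
#' @param ids identifiers (fish or population), recycled if length 1
#' @return data.frame with id, linf, k, t0, se_linf, se_k, se_t0, omega,
#'   n_points, converged, boot_reps
#' @export
vbgm_table <- function(fits, ids = names(fits)) {
  if (is.null(ids)) ids <- seq_along(fits)
  do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(id = as.character(ids[[i]]),
               linf = f$coefficients[["linf"]], k = f$coefficients[["k"]],
               t0 = f$coefficients[["t0"]],
               se_linf = f$se[["linf"]], se_k = f$se[["k"]],
               se_t0 = f$se[["t0"]],
               omega = f$omega, n_points = f$n_points,
               converged = f$converged,
               boot_reps = if (is.null(f$boot)) 0L else f$boot$reps,
               stringsAsFactors = FALSE)
  }))
}

#' Filter Von Bertalanffy fits by relative standard error
#'
#' A fit is retained only when SE(L_inf)/L_inf and SE(K)/K are both at most
#' `se_max_ratio` (default 25%); exceeding either marks a poor individual
#' fit whose parameters would distort downstream comparisons. The ratio is
#' not applied to t0, whose estimate near zero makes a relative SE
#' meaningless. Non-converged fits are never retained.
#'
#' @param fits data.frame as produced by [vbgm_table()]
#' @param se_max_ratio maximum allowed SE/estimate ratio (strictly greater
#'   excludes)
#' @return `fits` with a logical `retained` column added
#' @export
filter_fits <- function(fits, se_max_ratio = 0.25) {
  bad <- (fits$se_linf / fits$linf > se_max_ratio) |
    (fits$se_k / fits$k > se_max_ratio)
  fits$retained <- fits$converged & !is.na(bad) & !bad
  n_removed <- sum(fits$converged & !fits$retained)
  if (n_removed > 0) {
    message("filter_fits: removed ", n_removed,
            " converged fit(s) exceeding the ", 100 * se_max_ratio,
            "% relative-SE rule")
  }
  fits
}

## ---- vbgm_fit methods -----------------------------------------------------

#' @export
print.vbgm_fit <- function(x, ...) {
  cat("Von Bertalanffy growth model fit\n")
  if (!x$converged) {
    cat("  did not converge (", x$n_points, " points)\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  L_inf = %.1f mm  K = %.3f /yr  t0 = %.2f yr  (omega = %.1f mm/yr)\n",
              x$coefficients[["linf"]], x$coefficients[["k"]],
              x$coefficients[["t0"]], x$omega))
  cat(sprintf("  n = %d points; SEs %s\n", x$n_points,
              if (is.null(x$boot)) "asymptotic"
              else sprintf("from %d bootstrap replicates", x$boot$reps)))
  invisible(x)
}

#' @export
summary.vbgm_fit <- function(object, ...) {
  tab <- data.frame(
    estimate = object$coefficients,
    se = object$se,
    row.names = c("linf", "k", "t0"))
  out <- list(coefficients = tab, omega = object$omega,
              n_points = object$n_points, converged = object$converged,
              boot = object$boot,
              rse = if (object$converged)
                sqrt(sum(object$residuals^2) / (object$n_points - 3))
              else NA_real_)
  class(out) <- "summary.vbgm_fit"
  out
}

#' @export
print.summary.vbgm_fit <- function(x, ...) {
  cat("Von Bertalanffy growth model\n")
  print(round(x$coefficients, 4))
  cat(sprintf("omega = %.2f mm/yr; residual SE = %.2f mm on %d points\n",
              x$omega, x$rse, x$n_points))
  if (!is.null(x$boot)) {
    cat(sprintf("bootstrap: %d replicates, %d failed\n",
                x$boot$reps, x$boot$n_failed))
  }
  invisible(x)
}

#' @export
coef.vbgm_fit <- function(object, ...) object$coefficients

#' @export
#' @param newdata optional data.frame with an `age` column (or a numeric
#'   vector of ages); default: the fitted ages
#' @rdname fit_vbgm
predict.vbgm_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("predict: fit did not converge", call. = FALSE)
  age <- if (is.null(newdata)) object$data$age
  else if (is.numeric(newdata)) newdata
  else newdata$age
  cf <- object$coefficients
  cf[["linf"]] * (1 - exp(-cf[["k"]] * (age - cf[["t0"]])))
}

#' @export
residuals.vbgm_fit <- function(object, ...) object$residuals

#' @export
fitted.vbgm_fit <- function(object, ...) object$fitted

#' @export
plot.vbgm_fit <- function(x, ...) {
  if (!x$converged) stop("plot: fit did not converge", call. = FALSE)
  graphics::plot(x$data$age, x$data$length_mm, pch = 16,
                 col = grDevices::grey(0.4),
                 xlab = "Age (yr)", ylab = "Length (mm)", ...)
  ages <- seq(min(x$data$age), max(x$data$age), length.out = 200)
  graphics::lines(ages, predict(x, ages), lwd = 2)
  invisible(x)
}
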