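#' Ancestry-condition slope/intercept recovery experiment
#'
#' For each seed, simulates a stocked cohort whose true relative weight
#' follows Wr = intercept + slope * (percent local assignment) with Gaussian
#' residuals, fits the simple regression with [regress_wr()], and records
#' the fitted slope and intercept, their 95% confidence intervals, whether
#' each interval covers its generating value, and the adjusted R-squared.
#'
#' @param seeds integer vector of seeds, one replicate per seed
#' @param n fish per replicate
#' @param slope,intercept generating ancestry-condition line
#' @param sigma residual SD of Wr; default chosen with [wr_sigma_for_r2()]
#'   from `target_r2`
#' @param pct_range range of percent local assignment
#' @param target_r2 population adjusted R-squared used to set `sigma` when
#'   `sigma` is NULL
#' @return data.frame with one row per seed: slope, intercept, their CI
#'   bounds, covers_slope, covers_intercept, adj_r2, p
#' @export
ancestry_recovery_experiment <- function(seeds, n = 157, slope = 0.15,
                                         intercept = 88.6, sigma = NULL,
                                         pct_range = c(0, 100),
                                         target_r2 = 0.22) {
  if (is.null(sigma)) sigma <- wr_sigma_for_r2(slope, pct_range, target_r2)
  out <- lapply(seeds, function(s) {
    d <- simulate_wr_ancestry(n, slope, intercept, sigma, pct_range, seed = s)
    reg <- regress_wr(d$pct_local, d$wr)
    ci <- confint(reg)
    data.frame(seed = s, slope = reg$slope, intercept = reg$intercept,
               slope_lo = ci["slope", 1], slope_hi = ci["slope", 2],
               intercept_lo = ci["intercept", 1],
               intercept_hi = ci["intercept", 2],
               covers_slope = ci["slope", 1] <= slope & slope <= ci["slope", 2],
               covers_intercept = ci["intercept", 1] <= intercept &
                 intercept <= ci["intercept", 2],
               adj_r2 = reg$adj_r2, p = reg$p)
  })
  do.call(rbind, out)
}

#' Pooled-population Von Bertalanffy recovery experiment
#'
#' For each seed, simulates one lake's worth of back-calculated length-at-age
#' series on a known Von Bertalanffy curve with multiplicative observation
#' noise, fits the pooled population model (Ford-Walford starts, nonlinear
#' least squares, bootstrap SEs), and records the fitted L_inf and K
#' together with whether each lies within `k_se` bootstrap SEs of its
#' generating value.
#'
#' @param seeds integer vector of seeds, one simulated lake per seed
#' @param n_fish fish per lake
#' @param linf,k,t0 generating parameters
#' @param measurement_cv multiplicative observation noise on lengths
#' @param boot_reps bootstrap replicates for the SEs
#' @param k_se half-width of the recovery band in bootstrap SEs
#' @return data.frame with one row per seed: linf, k, se_linf, se_k,
#'   within_linf, within_k, converged
#' @export
vbgm_recovery_experiment <- function(seeds, n_fish = 30, linf = 464,
                                     k = 0.13, t0 = -0.43,
                                     measurement_cv = 0.02, boot_reps = 199,
                                     k_se = 3) {
  out <- lapply(seeds, function(s) {
    d <- simulate_length_at_age(n_fish, linf, k, t0,
                                measurement_cv = measurement_cv, seed = s)
    fit <- fit_vbgm(d$age, d$length_mm, boot_reps = boot_reps, seed = s + 1L)
    cf <- coef(fit)
    data.frame(seed = s, linf = cf[["linf"]], k = cf[["k"]],
               se_linf = fit$se[["linf"]], se_k = fit$se[["k"]],
               within_linf = abs(cf[["linf"]] - linf) <= k_se * fit$se[["linf"]],
               within_k = abs(cf[["k"]] - k) <= k_se * fit$se[["k"]],
               converged = fit$converged)
  })
  do.call(rbind, out)
}
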