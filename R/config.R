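#' Default lake design table
#'
#' A 2 ecotypes x stocked/unstocked survey design over ten small boreal
#' lakes, with the per-lake sample sizes of the study the generator
#' emulates. `n_sources` is the number of distinct hatchery source
#' populations that stocked the lake (0 for unstocked lakes).
#'
#' @return data.frame with columns name, ecotype, stocked, n_fish, n_sources
#' @export
default_lakes <- function() {
  data.frame(
    name = c("Desert", "Marguerite", "Opeongo", "Antoine", "Bondy", "Shirley",
             "Cayamant", "Cedres", "Louisa", "McFee"),
    ecotype = c("piscivorous", "piscivorous", "piscivorous",
                "planktivorous", "planktivorous", "planktivorous",
                "piscivorous", "piscivorous", "planktivorous", "planktivorous"),
    stocked = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    n_fish = c(22L, 32L, 26L, 28L, 30L, 18L, 84L, 77L, 75L, 84L),
    n_sources = c(0L, 0L, 0L, 0L, 0L, 0L, 2L, 2L, 2L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Default Von Bertalanffy cell means by ecotype and genetic origin
#'
#' Mean individual growth parameters for each ecotype x origin cell.
#' Stocked fish carry piscivorous hatchery genetics in both recipient
#' ecotypes, so they keep a large asymptotic length; hybrids are
#' intermediate; local fish follow their lake's ecotype. Values are on the
#' scale of published small-boreal-lake Lake Trout fits (L_inf in mm,
#' K in 1/yr, t0 in yr).
#'
#' @return data.frame with columns ecotype, origin, linf, k, t0
#' @export
default_vbgm_means <- function() {
  data.frame(
    ecotype = rep(c("piscivorous", "planktivorous"), each = 3),
    origin = rep(c("local", "hybrid", "stocked"), 2),
    linf = c(760, 667, 883, 471, 486, 591),
    k = c(0.11, 0.10, 0.10, 0.13, 0.13, 0.12),
    t0 = c(-0.1, -0.05, 0.0, -0.40, -0.30, -0.20),
    stringsAsFactors = FALSE
  )
}

#' Default length-otolith power law by ecotype
#'
#' Coefficients of L = u * S^v (L in mm, S in um) used to place annuli on
#' the otolith from the true length trajectory. Defaults differ by ecotype
#' so that ecotype-specific back-calculation regressions genuinely fit
#' better than a combined one.
#'
#' @return data.frame with columns ecotype, u, v
#' @export
default_otolith_power <- function() {
  data.frame(
    ecotype = c("piscivorous", "planktivorous"),
    u = c(0.27, 0.811),
    v = c(1.03, 0.85),
    stringsAsFactors = FALSE
  )
}

#' Default origin mixture per stocked lake
#'
#' Probabilities that a fish sampled in each stocked lake is of local,
#' hybrid or stocked genetic origin.
#'
#' @return data.frame with columns lake, p_local, p_hybrid, p_stocked
#' @export
default_origin_mix <- function() {
  data.frame(
    lake = c("McFee", "Cedres", "Cayamant", "Louisa"),
    p_local = c(0.552, 0.547, 0.392, 0.181),
    p_hybrid = c(0.254, 0.293, 0.203, 0.458),
    p_stocked = c(0.194, 0.160, 0.405, 0.361),
    stringsAsFactors = FALSE
  )
}

#' Default Beta shapes for local-ancestry Q by origin
#'
#' Local and stocked fish draw Q_local from Beta distributions concentrated
#' near 1 and 0 respectively; hybrids from a broad Beta truncated to
#' (0.10, 0.90), the admixture band that defines a hybrid.
#'
#' @return data.frame with columns origin, shape1, shape2
#' @export
default_q_beta <- function() {
  data.frame(
    origin = c("local", "hybrid", "stocked"),
    shape1 = c(60, 2, 1),
    shape2 = c(1, 2, 60),
    stringsAsFactors = FALSE
  )
}

#' Build and validate a synthetic cohort configuration
#'
#' Assembles the full set of parameters that define a synthetic two-ecotype
#' stocked/unstocked Lake Trout survey: the lake design, per ecotype x origin
#' Von Bertalanffy means with individual lognormal variation, the
#' length-otolith power law and its per-fish deviation, stocked-lake origin
#' mixtures, the generative model for admixture proportions Q and their
#' bootstrap SEs, the ancestry-condition relationship, the age distribution
#' and observation noise.
#'
#' @param lakes lake design table, see [default_lakes()]; optional columns
#'   `linf`, `k`, `t0` override the local-origin cell means for that lake
#' @param vbgm_means ecotype x origin growth-parameter cell means,
#'   see [default_vbgm_means()]
#' @param vbgm_cv lognormal coefficient of variation of individual L_inf and
#'   K around their cell means (dimensionless)
#' @param t0_jitter_sd SD (yr) of additive individual variation in t0
#' @param otolith_power per-ecotype (u, v) of L = u*S^v; a single-row table
#'   (or an unnamed length-2 numeric c(u, v)) is recycled to both ecotypes
#' @param otolith_noise_sd SD of the per-fish log-scale deviation shared by
#'   all annuli of one otolith (so BPH back-calculation stays exact per fish)
#' @param annulus_noise_sd SD of optional additional per-annulus log-scale
#'   measurement noise; default 0 (none)
#' @param origin_mix per stocked lake origin mixture, see
#'   [default_origin_mix()]
#' @param q_beta_params Beta shapes for Q_local by origin, see
#'   [default_q_beta()]
#' @param q_se_sd scale of the half-normal simulated bootstrap SE on Q
#' @param condition_slope named per-ecotype slope of true relative weight Wr
#'   on percent local assignment (Wr units per percent), stocked lakes only
#' @param condition_intercept named per-ecotype intercept of the same line
#' @param unstocked_wr_mean mean true Wr in unstocked lakes (ancestry there
#'   is uniformly local, so the ancestry line does not apply)
#' @param wr_noise_sd residual SD of true Wr
#' @param age_mean,age_sd,age_range parameters of the discretized truncated
#'   normal age-at-capture distribution (yr)
#' @param measurement_cv relative (lognormal) noise on observed total length
#' @param seed integer seed controlling every draw of the generator
#' @return an object of class `simulation_config`
#' @export
simulation_config <- function(lakes = default_lakes(),
                              vbgm_means = default_vbgm_means(),
                              vbgm_cv = 0.08,
                              t0_jitter_sd = 0.1,
                              otolith_power = default_otolith_power(),
                              otolith_noise_sd = 0.05,
                              annulus_noise_sd = 0,
                              origin_mix = default_origin_mix(),
                              q_beta_params = default_q_beta(),
                              q_se_sd = 0.01,
                              condition_slope = c(piscivorous = 0.03,
                                                  planktivorous = 0.15),
                              condition_intercept = c(piscivorous = 89.1,
                                                      planktivorous = 88.6),
                              unstocked_wr_mean = 100,
                              wr_noise_sd = 8.15,
                              age_mean = 12,
                              age_sd = 3.45,
                              age_range = c(4, 28),
                              measurement_cv = 0.02,
                              seed = 1L) {
  if (is.numeric(otolith_power) && length(otolith_power) == 2) {
    otolith_power <- data.frame(ecotype = c("piscivorous", "planktivorous"),
                                u = otolith_power[1], v = otolith_power[2])
  }
  if (nrow(otolith_power) == 1) {
    otolith_power <- data.frame(ecotype = c("piscivorous", "planktivorous"),
                                u = otolith_power$u, v = otolith_power$v)
  }
  cfg <- structure(list(
    lakes = lakes, vbgm_means = vbgm_means, vbgm_cv = vbgm_cv,
    t0_jitter_sd = t0_jitter_sd, otolith_power = otolith_power,
    otolith_noise_sd = otolith_noise_sd, annulus_noise_sd = annulus_noise_sd,
    origin_mix = origin_mix, q_beta_params = q_beta_params, q_se_sd = q_se_sd,
    condition_slope = condition_slope,
    condition_intercept = condition_intercept,
    unstocked_wr_mean = unstocked_wr_mean, wr_noise_sd = wr_noise_sd,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    measurement_cv = measurement_cv, seed = as.integer(seed)
  ), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

config_error <- function(field, why) {
  stop(sprintf("configuration error in field '%s': %s", field, why),
       call. = FALSE)
}

validate_simulation_config <- function(cfg) {
  lk <- cfg$lakes
  if (any(lk$n_fish <= 0)) config_error("lakes$n_fish", "all counts must be > 0")
  if (!all(lk$ecotype %in% c("piscivorous", "planktivorous"))) {
    config_error("lakes$ecotype", "must be 'piscivorous' or 'planktivorous'")
  }
  vm <- cfg$vbgm_means
  if (any(vm$linf <= 0)) config_error("vbgm_means$linf", "L_inf must be > 0")
  if (any(vm$k <= 0)) config_error("vbgm_means$k", "K must be > 0")
  op <- cfg$otolith_power
  if (any(op$u <= 0)) config_error("otolith_power$u", "u must be > 0")
  if (any(op$v <= 0)) config_error("otolith_power$v", "v must be > 0")
  om <- cfg$origin_mix
  tot <- om$p_local + om$p_hybrid + om$p_stocked
  if (any(abs(tot - 1) > 1e-9)) {
    config_error("origin_mix",
                 sprintf("mixture weights must sum to 1 (lake %s sums to %.6g)",
                         om$lake[which.max(abs(tot - 1))],
                         tot[which.max(abs(tot - 1))]))
  }
  if (any(om$p_local < 0 | om$p_hybrid < 0 | om$p_stocked < 0)) {
    config_error("origin_mix", "mixture weights must be non-negative")
  }
  qb <- cfg$q_beta_params
  if (any(qb$shape1 <= 0 | qb$shape2 <= 0)) {
    config_error("q_beta_params", "Beta shapes must be > 0")
  }
  for (f in c("vbgm_cv", "otolith_noise_sd", "annulus_noise_sd", "q_se_sd",
              "wr_noise_sd", "measurement_cv", "t0_jitter_sd")) {
    if (cfg[[f]] < 0) config_error(f, "must be >= 0")
  }
  if (cfg$age_range[1] < 1 || cfg$age_range[2] < cfg$age_range[1]) {
    config_error("age_range", "must satisfy 1 <= min <= max")
  }
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' The file holds scalar fields directly and the tabular fields
#' (lakes, vbgm_means, otolith_power, origin_mix, q_beta_params) as lists of
#' records. Missing fields fall back to the package defaults.
#'
#' @param path path to a YAML file
#' @return a validated `simulation_config`
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_df <- function(x) if (is.null(x)) NULL else
    do.call(rbind, lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  args <- raw
  for (f in c("lakes", "vbgm_means", "otolith_power", "origin_mix",
              "q_beta_params")) {
    if (!is.null(raw[[f]])) args[[f]] <- as_df(raw[[f]])
  }
  for (f in c("condition_slope", "condition_intercept")) {
    if (!is.null(raw[[f]])) args[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$age_range)) args$age_range <- unlist(raw$age_range)
  do.call(simulation_config, args[names(args) %in%
                                    names(formals(simulation_config))])
}
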