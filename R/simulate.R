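#' Map a true length trajectory onto otolith annulus radii
#'
#' Inverts the length-otolith power law L = u * S^v, placing one annulus per
#' completed year of growth at radius S_t = (L_t/u)^(1/v) * exp(deviation).
#' The per-fish `deviation` is shared by every annulus and by the capture
#' radius, so back-calculation under the body proportional hypothesis with
#' the same exponent v recovers the trajectory exactly: the deviation cancels
#' in the ratio S_i/S.
#'
#' @param lengths_mm true length at each completed age, mm (all > 0)
#' @param u,v power-law coefficients (> 0), L in mm and S in um
#' @param deviation per-fish log-scale deviation (scalar)
#' @param capture_length_mm length at capture used for the capture radius;
#'   defaults to the last trajectory value
#' @return list of class `otolith_profile` with elements `radii_um` and
#'   `capture_radius_um`
#' @export
otolith_from_trajectory <- function(lengths_mm, u, v, deviation = 0,
                                    capture_length_mm = max(lengths_mm)) {
  if (any(lengths_mm <= 0) || capture_length_mm <= 0) {
    stop("otolith_from_trajectory: lengths must be positive", call. = FALSE)
  }
  if (u <= 0 || v <= 0) {
    stop("otolith_from_trajectory: power-law coefficients must be positive",
         call. = FALSE)
  }
  structure(list(
    radii_um = (lengths_mm / u)^(1 / v) * exp(deviation),
    capture_radius_um = (capture_length_mm / u)^(1 / v) * exp(deviation)
  ), class = "otolith_profile")
}

#' True relative weight and weight from length and ancestry
#'
#' In stocked lakes the true condition index follows the ecotype-specific
#' ancestry line Wr = intercept + slope * (100 * Q_local) + noise; in
#' unstocked lakes ancestry is uniformly local and Wr is drawn around
#' `unstocked_wr_mean`. Weight is then Ws(TL) * Wr / 100 with Ws from the
#' species standard-weight equation ([standard_weight()]).
#'
#' @param tl_mm total length, mm (> 0)
#' @param q_local proportion of local genetic assignment in [0, 1]
#' @param ecotype "piscivorous" or "planktivorous"
#' @param config a [simulation_config()]
#' @param stocked logical; whether the fish's lake is stocked
#' @param wr_noise realized residual(s) to add to the true Wr (default 0)
#' @return numeric weight in g, with the realized true Wr as attribute
#'   `"wr_true"`
#' @export
assign_weight <- function(tl_mm, q_local, ecotype, config, stocked = TRUE,
                          wr_noise = 0) {
  if (any(tl_mm <= 0)) stop("assign_weight: TL must be > 0", call. = FALSE)
  wr <- ifelse(stocked,
               config$condition_intercept[ecotype] +
                 config$condition_slope[ecotype] * (100 * q_local),
               config$unstocked_wr_mean) + wr_noise
  w <- standard_weight(tl_mm) * wr / 100
  attr(w, "wr_true") <- unname(wr)
  w
}

## Discretized normal ages, redrawn until inside [min, max].
draw_ages <- function(n, mean, sd, range) {
  ages <- integer(0)
  while (length(ages) < n) {
    a <- round(stats::rnorm(n, mean, sd))
    ages <- c(ages, a[a >= range[1] & a <= range[2]])
  }
  as.integer(ages[seq_len(n)])
}

## Hybrid Q_local: Beta truncated to (0.10, 0.90) by rejection.
draw_q_local <- function(origin, qb) {
  row <- qb[qb$origin == origin, ]
  if (nrow(row) != 1) config_error("q_beta_params",
                                   paste("no Beta shapes for origin", origin))
  repeat {
    q <- stats::rbeta(1, row$shape1, row$shape2)
    if (origin != "hybrid" || (q > 0.10 && q < 0.90)) return(q)
  }
}

#' Simulate a complete synthetic stocking survey
#'
#' Generates, from one seed, every table the analysis pipeline consumes:
#' a per-fish phenotype table, per-fish otolith annulus profiles, admixture
#' records for fish in stocked lakes, and the ground truth used by recovery
#' tests. Each fish receives individual Von Bertalanffy parameters
#' (lognormal variation around its ecotype x origin cell mean), an integer
#' age from a discretized truncated normal, a true length trajectory
#' L_t = L_inf * (1 - exp(-K (t - t0))) over completed ages, an otolith
#' whose annuli invert the ecotype's length-radius power law with one shared
#' per-fish deviation, an ancestry proportion Q_local with a simulated
#' bootstrap SE, and a weight tied to ancestry through the relative-weight
#' condition line.
#'
#' Capture is taken to occur half a growth season after the last completed
#' annulus, so the capture radius always exceeds the last annulus radius.
#' Fish in unstocked lakes have Q_local = 1 by construction and no
#' admixture record.
#'
#' @param config a [simulation_config()]
#' @return list of class `trout_cohort` with data.frames `fish`, `otoliths`
#'   (long, one row per annulus plus one capture-radius row per fish),
#'   `admixture`, `truth`, `trajectories`, and the `config`
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  lakes <- config$lakes
  vm <- config$vbgm_means
  fish <- truth <- traj <- oto <- adm <- list()
  id <- 0L

  for (li in seq_len(nrow(lakes))) {
    lake <- lakes[li, ]
    n <- lake$n_fish
    if (lake$stocked) {
      mix <- config$origin_mix[config$origin_mix$lake == lake$name, ]
      if (nrow(mix) != 1) config_error("origin_mix",
                                       paste("no mixture for stocked lake", lake$name))
      origins <- sample(c("local", "hybrid", "stocked"), n, replace = TRUE,
                        prob = c(mix$p_local, mix$p_hybrid, mix$p_stocked))
    } else {
      origins <- rep("local", n)
    }
    sexes <- sample(c("female", "male"), n, replace = TRUE)
    ages <- draw_ages(n, config$age_mean, config$age_sd, config$age_range)
    pw <- config$otolith_power[config$otolith_power$ecotype == lake$ecotype, ]

    for (j in seq_len(n)) {
      id <- id + 1L
      fid <- sprintf("F%04d", id)
      origin <- origins[j]
      cell <- vm[vm$ecotype == lake$ecotype & vm$origin == origin, ]
      if (nrow(cell) != 1) config_error("vbgm_means",
                                        paste("no cell for", lake$ecotype, origin))
      # optional per-lake override of the local-origin growth means
      if (origin == "local" && !is.null(lake$linf) && is.finite(lake$linf)) {
        cell$linf <- lake$linf; cell$k <- lake$k; cell$t0 <- lake$t0
      }
      linf <- cell$linf * exp(stats::rnorm(1, 0, config$vbgm_cv))
      k <- cell$k * exp(stats::rnorm(1, 0, config$vbgm_cv))
      t0 <- min(cell$t0 + stats::rnorm(1, 0, config$t0_jitter_sd), 0.9)
      age <- ages[j]
      t <- seq_len(age)
      L_t <- linf * (1 - exp(-k * (t - t0)))
      L_cap <- linf * (1 - exp(-k * (age + 0.5 - t0)))

      dev <- stats::rnorm(1, 0, config$otolith_noise_sd)
      prof <- otolith_from_trajectory(L_t, pw$u, pw$v, dev, L_cap)
      radii <- prof$radii_um
      if (config$annulus_noise_sd > 0) {
        radii <- radii * exp(stats::rnorm(age, 0, config$annulus_noise_sd))
      }

      tl_obs <- L_cap * exp(stats::rnorm(1, 0, config$measurement_cv))
      q_local <- if (lake$stocked) draw_q_local(origin, config$q_beta_params) else 1
      wr_noise <- stats::rnorm(1, 0, config$wr_noise_sd)
      w <- assign_weight(tl_obs, q_local, lake$ecotype, config,
                         stocked = lake$stocked, wr_noise = wr_noise)

      fish[[id]] <- data.frame(
        fish_id = fid, lake = lake$name, ecotype = lake$ecotype,
        stocked = lake$stocked, sex = sexes[j], age_yr = age,
        tl_mm = tl_obs, weight_g = as.numeric(w), stringsAsFactors = FALSE)
      oto[[id]] <- data.frame(
        fish_id = fid,
        annulus_index = c(t, NA_integer_),
        radius_um = c(radii, prof$capture_radius_um),
        is_capture_radius = c(rep(FALSE, age), TRUE), stringsAsFactors = FALSE)
      traj[[id]] <- data.frame(fish_id = fid, age = t, length_mm = L_t,
                               stringsAsFactors = FALSE)
      truth[[id]] <- data.frame(
        fish_id = fid, lake = lake$name, ecotype = lake$ecotype,
        origin = origin, sex = sexes[j], age_yr = age,
        linf = linf, k = k, t0 = t0, q_local = q_local,
        wr_true = attr(w, "wr_true"), stringsAsFactors = FALSE)
      if (lake$stocked) {
        se <- abs(stats::rnorm(1, 0, config$q_se_sd))
        q_src <- 1 - q_local
        split <- if (lake$n_sources >= 2) stats::runif(1) else 1
        adm[[length(adm) + 1L]] <- data.frame(
          fish_id = fid, q_local = q_local,
          q_source_1 = q_src * split, q_source_2 = q_src * (1 - split),
          se = se, stringsAsFactors = FALSE)
      }
    }
  }

  structure(list(
    fish = do.call(rbind, fish),
    otoliths = do.call(rbind, oto),
    admixture = if (length(adm)) do.call(rbind, adm) else
      data.frame(fish_id = character(0), q_local = numeric(0),
                 q_source_1 = numeric(0), q_source_2 = numeric(0),
                 se = numeric(0)),
    truth = do.call(rbind, truth),
    trajectories = do.call(rbind, traj),
    config = config
  ), class = "trout_cohort")
}

#' @export
print.trout_cohort <- function(x, ...) {
  cat("Synthetic Lake Trout cohort:", nrow(x$fish), "fish in",
      nrow(x$config$lakes), "lakes\n")
  cat("  stocked-lake fish with admixture records:", nrow(x$admixture), "\n")
  cat("  otolith annulus measurements:",
      sum(!x$otoliths$is_capture_radius), "\n")
  invisible(x)
}

#' Write a synthetic cohort to delimited text tables
#'
#' Writes fish.csv, otoliths.csv, admixture.csv and truth.csv (ground truth)
#' into `dir` as comma-separated UTF-8 tables with header rows.
#'
#' @param cohort a `trout_cohort` from [simulate_cohort()]
#' @param dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fish = file.path(dir, "fish.csv"),
             otoliths = file.path(dir, "otoliths.csv"),
             admixture = file.path(dir, "admixture.csv"),
             truth = file.path(dir, "truth.csv"))
  write_csv_atomic(cohort$fish, paths["fish"])
  write_csv_atomic(cohort$otoliths, paths["otoliths"])
  write_csv_atomic(cohort$admixture, paths["admixture"])
  write_csv_atomic(cohort$truth, paths["truth"])
  invisible(paths)
}

#' Simulate relative weight against percent local ancestry
#'
#' Direct generator for the ancestry-condition regression experiment:
#' percent local assignment uniform on `pct_range` and
#' Wr = intercept + slope * pct + Gaussian residual.
#'
#' @param n number of fish
#' @param slope,intercept generating line (Wr units per percent; Wr units)
#' @param sigma residual SD of Wr; see [wr_sigma_for_r2()] to choose it from
#'   a target adjusted R-squared
#' @param pct_range range of percent local assignment
#' @param seed optional integer seed
#' @return data.frame with columns pct_local, wr
#' @export
simulate_wr_ancestry <- function(n, slope, intercept, sigma,
                                 pct_range = c(0, 100), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pct <- stats::runif(n, pct_range[1], pct_range[2])
  data.frame(pct_local = pct,
             wr = intercept + slope * pct + stats::rnorm(n, 0, sigma))
}

#' Residual SD giving a target R-squared for the ancestry line
#'
#' For a uniform predictor on `pct_range`, the population R-squared of the
#' simple regression is var_signal / (var_signal + sigma^2) with
#' var_signal = slope^2 * range^2 / 12; this solves for sigma.
#'
#' @param slope generating slope
#' @param pct_range predictor range
#' @param r2 target (population) R-squared in (0, 1)
#' @return residual SD
#' @export
wr_sigma_for_r2 <- function(slope, pct_range, r2) {
  stopifnot(r2 > 0, r2 < 1)
  vs <- slope^2 * diff(range(pct_range))^2 / 12
  sqrt(vs * (1 / r2 - 1))
}

#' Simulate pooled length-at-age data for one population
#'
#' Draws integer ages at capture from the study's discretized truncated
#' normal and, for each fish, a back-calculated length at every completed
#' age on a shared Von Bertalanffy curve with multiplicative lognormal
#' observation noise. `vbgm_cv` optionally adds lognormal individual
#' variation in L_inf and K around the population values.
#'
#' @param n_fish number of fish
#' @param linf,k,t0 population Von Bertalanffy parameters (mm, 1/yr, yr)
#' @param measurement_cv relative observation noise on each length
#' @param vbgm_cv individual lognormal CV of L_inf and K (default 0: all
#'   fish share the population curve)
#' @param age_mean,age_sd,age_range age-at-capture distribution
#' @param seed optional integer seed
#' @return data.frame with columns fish_id, age, length_mm
#' @export
simulate_length_at_age <- function(n_fish, linf, k, t0,
                                   measurement_cv = 0.02, vbgm_cv = 0,
                                   age_mean = 12, age_sd = 3.45,
                                   age_range = c(4, 28), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ages <- draw_ages(n_fish, age_mean, age_sd, age_range)
  out <- lapply(seq_len(n_fish), function(i) {
    li <- linf * exp(stats::rnorm(1, 0, vbgm_cv))
    ki <- k * exp(stats::rnorm(1, 0, vbgm_cv))
    t <- seq_len(ages[i])
    L <- li * (1 - exp(-ki * (t - t0)))
    data.frame(fish_id = sprintf("F%04d", i), age = t,
               length_mm = L * exp(stats::rnorm(length(t), 0, measurement_cv)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
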