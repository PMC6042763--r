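#' Assemble a pipeline configuration
#'
#' Centralizes every tunable of the end-to-end analysis: the synthetic
#' cohort configuration, classification thresholds, bootstrap replicates,
#' the relative-SE retention rule and output location. All tables use one
#' flat CSV dialect (comma separator, header row, UTF-8, "." decimal) with
#' units encoded in column names (tl_mm, radius_um, weight_g).
#'
#' @param out_dir directory where stage tables are written
#' @param sim a [simulation_config()] for the simulate stage
#' @param q_low,q_high origin-classification thresholds (0 < low < high < 1)
#' @param symmetric_se local-boundary SE direction, see [classify_origin()]
#' @param boot_reps bootstrap replicates for Von Bertalanffy SEs (>= 1)
#' @param se_filter relative-SE retention threshold for individual fits
#' @param min_points minimum distinct ages for an individual fit
#' @param seed pipeline seed (growth-stage bootstrap)
#' @param verbose print stage progress
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir, sim = simulation_config(),
                            q_low = 0.10, q_high = 0.90,
                            symmetric_se = FALSE, boot_reps = 999,
                            se_filter = 0.25, min_points = 4,
                            seed = 1L, verbose = TRUE) {
  if (!(q_low > 0 && q_high < 1 && q_low < q_high)) {
    config_error("q_low/q_high", "must satisfy 0 < q_low < q_high < 1")
  }
  if (boot_reps < 1) config_error("boot_reps", "must be >= 1")
  structure(list(out_dir = out_dir, sim = sim, q_low = q_low,
                 q_high = q_high, symmetric_se = symmetric_se,
                 boot_reps = boot_reps, se_filter = se_filter,
                 min_points = min_points, seed = as.integer(seed),
                 verbose = verbose),
            class = "pipeline_config")
}

pipeline_stages <- c("simulate", "assign", "backcalc", "growth",
                     "condition", "models")

log_info <- function(config, ...) {
  if (isTRUE(config$verbose)) message(...)
}

update_manifest <- function(config, stage, tables, warnings = character(0)) {
  path <- file.path(config$out_dir, "manifest.json")
  manifest <- if (file.exists(path)) jsonlite::read_json(path) else list()
  manifest[[stage]] <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    row_counts = lapply(tables, nrow),
    warnings = as.list(warnings),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  tmp <- tempfile(tmpdir = config$out_dir, fileext = ".json")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, path)
  invisible(manifest)
}

#' Run one pipeline stage
#'
#' Stages and their file contracts (all under `config$out_dir`):
#' \describe{
#'   \item{simulate}{writes fish.csv, otoliths.csv, admixture.csv, truth.csv}
#'   \item{assign}{reads admixture.csv, fish.csv; writes origins.csv and
#'     origin_summary.csv}
#'   \item{backcalc}{reads fish.csv, otoliths.csv; writes backcalc.csv and
#'     power.csv (per-ecotype regression coefficients)}
#'   \item{growth}{reads backcalc.csv, fish.csv; writes vbgm_individual.csv
#'     (bootstrap SEs, retention flags) and vbgm_population.csv (pooled
#'     per-lake fits)}
#'   \item{condition}{reads fish.csv and, if present, origins.csv; writes
#'     condition.csv and condition_tests.csv (Welch test and Wr regressions)}
#'   \item{models}{reads the upstream tables; writes mixed_models.csv}
#' }
#' Outputs are written atomically and recorded, with row counts and
#' warnings, in manifest.json. A missing upstream table raises an error
#' naming the stage that produces it.
#'
#' @param stage one of simulate, assign, backcalc, growth, condition, models
#' @param config a [pipeline_config()]
#' @return invisibly, a named list of the stage's output tables
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, pipeline_stages)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(stage,
                simulate = stage_simulate(config),
                assign = stage_assign(config),
                backcalc = stage_backcalc(config),
                growth = stage_growth(config),
                condition = stage_condition(config),
                models = stage_models(config))
  update_manifest(config, stage, out$tables, out$warnings)
  invisible(out$tables)
}

#' Run the full pipeline
#'
#' Chains simulate, assign, backcalc, growth, condition and models on one
#' seeded configuration. Rerunning with the same configuration reproduces
#' byte-identical tables.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, the manifest path
#' @export
run_pipeline <- function(config) {
  for (stage in pipeline_stages) {
    log_info(config, "stage: ", stage)
    run_stage(stage, config)
  }
  invisible(file.path(config$out_dir, "manifest.json"))
}

stage_simulate <- function(config) {
  cohort <- simulate_cohort(config$sim)
  write_cohort(cohort, config$out_dir)
  list(tables = list(fish = cohort$fish, otoliths = cohort$otoliths,
                     admixture = cohort$admixture, truth = cohort$truth))
}

stage_assign <- function(config) {
  adm <- read_table_checked(file.path(config$out_dir, "admixture.csv"),
                            c("fish_id", "q_local", "q_source_1",
                              "q_source_2", "se"), "simulate")
  fish <- read_table_checked(file.path(config$out_dir, "fish.csv"),
                             c("fish_id", "lake"), "simulate")
  q_src <- adm$q_source_1 + adm$q_source_2
  origin <- classify_origin(pmin(pmax(q_src, 0), 1), adm$se,
                            q_low = config$q_low, q_high = config$q_high,
                            symmetric_se = config$symmetric_se)
  origins <- data.frame(fish_id = adm$fish_id, q_source = q_src,
                        se = adm$se, origin = as.character(origin),
                        stringsAsFactors = FALSE)
  merged <- merge(origins, fish[, c("fish_id", "lake")], by = "fish_id")
  summary <- summarize_origins(merged$origin, merged$lake)
  write_csv_atomic(origins, file.path(config$out_dir, "origins.csv"))
  write_csv_atomic(summary, file.path(config$out_dir, "origin_summary.csv"))
  list(tables = list(origins = origins, origin_summary = summary))
}

stage_backcalc <- function(config) {
  fish <- read_table_checked(file.path(config$out_dir, "fish.csv"),
                             c("fish_id", "ecotype", "tl_mm"), "simulate")
  oto <- read_table_checked(file.path(config$out_dir, "otoliths.csv"),
                            c("fish_id", "annulus_index", "radius_um",
                              "is_capture_radius"), "simulate")
  bc <- back_calculate_cohort(fish, oto)
  pf <- attr(bc, "power_fits")
  power <- do.call(rbind, lapply(names(pf), function(e) {
    data.frame(ecotype = e, u = pf[[e]]$u, v = pf[[e]]$v, r2 = pf[[e]]$r2,
               n = pf[[e]]$n, stringsAsFactors = FALSE)
  }))
  excl <- attr(bc, "excluded")
  write_csv_atomic(bc, file.path(config$out_dir, "backcalc.csv"))
  write_csv_atomic(power, file.path(config$out_dir, "power.csv"))
  list(tables = list(backcalc = bc, power = power),
       warnings = if (length(excl)) paste("excluded non-monotonic fish:",
                                          paste(excl, collapse = ",")))
}

stage_growth <- function(config) {
  bc <- read_table_checked(file.path(config$out_dir, "backcalc.csv"),
                           c("fish_id", "age", "length_mm"), "backcalc")
  fish <- read_table_checked(file.path(config$out_dir, "fish.csv"),
                             c("fish_id", "lake"), "simulate")
  set.seed(config$seed)
  by_fish <- split(bc, bc$fish_id)
  eligible <- names(by_fish)[vapply(by_fish, function(d)
    length(unique(d$age)) >= config$min_points, logical(1))]
  ind_fits <- lapply(by_fish[eligible], function(d) {
    fit_vbgm(d$age, d$length_mm, boot_reps = config$boot_reps)
  })
  ind <- filter_fits(vbgm_table(ind_fits, eligible),
                     se_max_ratio = config$se_filter)
  log_info(config, "growth: ", sum(!ind$retained), " of ", nrow(ind),
           " individual fits removed by the ", 100 * config$se_filter,
           "% relative-SE rule")
  bc_lake <- merge(bc, fish[, c("fish_id", "lake")], by = "fish_id")
  pop_fits <- lapply(split(bc_lake, bc_lake$lake), function(d) {
    fit_vbgm(d$age, d$length_mm, boot_reps = config$boot_reps)
  })
  pop <- vbgm_table(pop_fits)
  write_csv_atomic(ind, file.path(config$out_dir, "vbgm_individual.csv"))
  write_csv_atomic(pop, file.path(config$out_dir, "vbgm_population.csv"))
  list(tables = list(vbgm_individual = ind, vbgm_population = pop))
}

stage_condition <- function(config) {
  fish <- read_table_checked(file.path(config$out_dir, "fish.csv"),
                             c("fish_id", "lake", "ecotype", "stocked",
                               "age_yr", "tl_mm", "weight_g"), "simulate")
  fish$ws_g <- standard_weight(fish$tl_mm)
  fish$wr <- relative_weight(fish$weight_g, fish$ws_g)
  cond <- fish[, c("fish_id", "ws_g", "wr")]
  write_csv_atomic(cond, file.path(config$out_dir, "condition.csv"))

  tests <- list()
  add <- function(response, predictor, subset, reg) {
    tests[[length(tests) + 1L]] <<- data.frame(
      response = response, predictor = predictor, subset = subset,
      slope = reg$slope, intercept = reg$intercept, p = reg$p,
      adj_r2 = reg$adj_r2, n = reg$n, stringsAsFactors = FALSE)
  }
  uns <- fish[!fish$stocked, ]
  if (nrow(uns) >= 3) {
    add("wr", "tl_mm", "unstocked", regress_wr(uns$tl_mm, uns$wr))
    add("wr", "age_yr", "unstocked", regress_wr(uns$age_yr, uns$wr))
  }
  welch <- NULL
  if (all(table(uns$ecotype) >= 2) && length(unique(uns$ecotype)) == 2) {
    wt <- welch_test(uns$wr[uns$ecotype == "piscivorous"],
                     uns$wr[uns$ecotype == "planktivorous"])
    welch <- data.frame(test = "welch_wr_ecotypes_unstocked",
                        statistic = wt$statistic, df = wt$df, p = wt$p.value,
                        stringsAsFactors = FALSE)
  }
  origins_path <- file.path(config$out_dir, "origins.csv")
  if (file.exists(origins_path)) {
    org <- utils::read.csv(origins_path, stringsAsFactors = FALSE)
    st <- merge(fish[fish$stocked, ], org, by = "fish_id")
    st$pct_local <- 100 * (1 - st$q_source)
    for (eco in unique(st$ecotype)) {
      g <- st[st$ecotype == eco, ]
      if (nrow(g) >= 3) {
        add("wr", "pct_local", eco, regress_wr(g$pct_local, g$wr))
        hyb <- g$origin == "hybrid"
        if (sum(hyb) >= 3) {
          add("wr", "pct_local", paste0(eco, ":hybrid"),
              regress_wr(g$pct_local, g$wr, subset = hyb))
        }
      }
    }
  }
  tests <- do.call(rbind, tests)
  write_csv_atomic(tests, file.path(config$out_dir, "condition_tests.csv"))
  if (!is.null(welch)) {
    write_csv_atomic(welch, file.path(config$out_dir, "condition_welch.csv"))
  }
  list(tables = list(condition = cond, condition_tests = tests))
}

stage_models <- function(config) {
  fish <- read_table_checked(file.path(config$out_dir, "fish.csv"),
                             c("fish_id", "lake", "ecotype", "stocked",
                               "sex", "age_yr", "tl_mm"), "simulate")
  fits <- list()
  for (resp in c("tl_mm", "age_yr")) {
    fits[[resp]] <- fit_mixed(fish, resp, nested = "stocking")
  }
  origins_path <- file.path(config$out_dir, "origins.csv")
  vbgm_path <- file.path(config$out_dir, "vbgm_individual.csv")
  cond_path <- file.path(config$out_dir, "condition.csv")
  if (file.exists(origins_path) && file.exists(vbgm_path) &&
      file.exists(cond_path)) {
    org <- utils::read.csv(origins_path, stringsAsFactors = FALSE)
    vb <- utils::read.csv(vbgm_path, stringsAsFactors = FALSE)
    cond <- utils::read.csv(cond_path, stringsAsFactors = FALSE)
    names(vb)[names(vb) == "id"] <- "fish_id"
    m <- merge(fish[fish$stocked, ], org[, c("fish_id", "origin")],
               by = "fish_id")
    m <- merge(m, cond, by = "fish_id")
    m <- merge(m, vb[vb$retained, c("fish_id", "linf", "omega")],
               by = "fish_id", all.x = TRUE)
    if (length(unique(m$lake)) >= 2) {
      for (resp in c("linf", "omega", "wr")) {
        if (sum(stats::complete.cases(m[[resp]])) >= 10) {
          fits[[resp]] <- fit_mixed(m, resp, nested = "origin")
        }
      }
    }
  }
  report <- report_tables(fits)
  write_csv_atomic(report, file.path(config$out_dir, "mixed_models.csv"))
  list(tables = list(mixed_models = report))
}

#' Validate pipeline tables
#'
#' Report-only checks of the file contracts: required columns, plausible
#' unit ranges (total length within 100-1000 mm), positive and
#' monotonically increasing annulus radii per fish, and admixture rows
#' summing to 1.
#'
#' @param dir directory holding the pipeline tables
#' @return data.frame of violations (table, rule, id, message); zero rows
#'   when everything passes
#' @export
validate_tables <- function(dir) {
  v <- list()
  flag <- function(table, rule, id, msg) {
    v[[length(v) + 1L]] <<- data.frame(table = table, rule = rule, id = id,
                                       message = msg, stringsAsFactors = FALSE)
  }
  fish_path <- file.path(dir, "fish.csv")
  if (file.exists(fish_path)) {
    fish <- utils::read.csv(fish_path, stringsAsFactors = FALSE)
    need <- c("fish_id", "lake", "ecotype", "stocked", "sex", "age_yr",
              "tl_mm", "weight_g")
    for (col in setdiff(need, names(fish))) {
      flag("fish.csv", "column_missing", col, "required column absent")
    }
    if ("tl_mm" %in% names(fish)) {
      bad <- fish$fish_id[fish$tl_mm < 100 | fish$tl_mm > 1000]
      for (id in bad) flag("fish.csv", "tl_range", id,
                           "total length outside plausible 100-1000 mm band")
    }
  }
  oto_path <- file.path(dir, "otoliths.csv")
  if (file.exists(oto_path)) {
    oto <- utils::read.csv(oto_path, stringsAsFactors = FALSE)
    if (any(oto$radius_um <= 0)) {
      for (id in unique(oto$fish_id[oto$radius_um <= 0])) {
        flag("otoliths.csv", "radius_positive", id, "non-positive radius")
      }
    }
    ann <- oto[!oto$is_capture_radius, ]
    for (id in unique(ann$fish_id)) {
      a <- ann[ann$fish_id == id, ]
      a <- a[order(a$annulus_index), ]
      if (is.unsorted(a$radius_um, strictly = TRUE)) {
        flag("otoliths.csv", "radius_monotonic", id,
             "annulus radii not strictly increasing")
      }
    }
  }
  adm_path <- file.path(dir, "admixture.csv")
  if (file.exists(adm_path)) {
    adm <- utils::read.csv(adm_path, stringsAsFactors = FALSE)
    if (nrow(adm) > 0) {
      tot <- adm$q_local + adm$q_source_1 + adm$q_source_2
      for (i in which(abs(tot - 1) > 1e-6)) {
        flag("admixture.csv", "q_normalized", adm$fish_id[i],
             sprintf("Q proportions sum to %.4f, not 1", tot[i]))
      }
    }
  }
  if (length(v) == 0) {
    return(data.frame(table = character(0), rule = character(0),
                      id = character(0), message = character(0)))
  }
  do.call(rbind, v)
}
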