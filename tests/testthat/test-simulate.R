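test_that("the generator is deterministic under a fixed seed", {
  cfg <- simulation_config(lakes = tiny_lakes(), seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$fish, b$fish)
  expect_identical(a$otoliths, b$otoliths)
  expect_identical(a$admixture, b$admixture)
  expect_identical(a$truth, b$truth)
})

test_that("cohort structure matches the survey design", {
  cfg <- simulation_config(lakes = tiny_lakes(), seed = 3)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$fish), sum(cfg$lakes$n_fish))
  expect_equal(as.integer(table(co$fish$lake)[cfg$lakes$name]),
               cfg$lakes$n_fish)
  # one annulus per completed year plus one capture-radius row per fish
  ann <- co$otoliths[!co$otoliths$is_capture_radius, ]
  expect_equal(as.integer(table(ann$fish_id)[co$fish$fish_id]),
               co$fish$age_yr)
  expect_equal(sum(co$otoliths$is_capture_radius), nrow(co$fish))
  # admixture records exist exactly for stocked-lake fish
  stocked_ids <- co$fish$fish_id[co$fish$stocked]
  expect_setequal(co$admixture$fish_id, stocked_ids)
  # unstocked fish are fully local by construction
  expect_true(all(co$truth$q_local[!co$fish$stocked] == 1))
  # ages respect the discretized truncated normal support
  expect_true(all(co$fish$age_yr >= cfg$age_range[1] &
                    co$fish$age_yr <= cfg$age_range[2]))
  expect_true(all(co$fish$age_yr == round(co$fish$age_yr)))
})

test_that("noiseless limit reproduces the true trajectories exactly", {
  cfg <- simulation_config(lakes = tiny_lakes(4L, 6L),
                           measurement_cv = 0, otolith_noise_sd = 0,
                           wr_noise_sd = 0, seed = 9)
  co <- simulate_cohort(cfg)
  # observed TL equals the true capture length (trajectory at age + 0.5)
  L_cap <- co$truth$linf *
    (1 - exp(-co$truth$k * (co$truth$age_yr + 0.5 - co$truth$t0)))
  expect_equal(co$fish$tl_mm, L_cap, tolerance = 1e-12)
  # BPH back-calculation with the estimated exponent recovers every true
  # length: with zero otolith noise the capture points sit exactly on the
  # power law, so v is estimated exactly and the deviation cancels
  bc <- back_calculate_cohort(co$fish, co$otoliths)
  m <- merge(bc, co$trajectories, by = c("fish_id", "age"))
  expect_equal(m$length_mm.x, m$length_mm.y, tolerance = 1e-9)
})

test_that("otolith placement inverts the length-radius power law", {
  # identity mapping
  p <- otolith_from_trajectory(c(100, 200), u = 1, v = 1, deviation = 0)
  expect_equal(p$radii_um, c(100, 200))
  # direct scalar evaluation of (L/u)^(1/v)
  p2 <- otolith_from_trajectory(500, u = 0.27, v = 1.03)
  expect_equal(p2$radii_um, (500 / 0.27)^(1 / 1.03), tolerance = 1e-12)
  # round trip through BPH is an algebraic inverse, deviation included
  L_t <- c(120, 210, 280, 330)
  p3 <- otolith_from_trajectory(L_t, u = 0.4, v = 0.9, deviation = 0.3,
                                capture_length_mm = 350)
  back <- back_calculate(350, p3$capture_radius_um, p3$radii_um, v = 0.9)
  expect_equal(back, L_t, tolerance = 1e-9)
  expect_error(otolith_from_trajectory(c(-1, 10), 1, 1), "positive")
})

test_that("assign_weight follows the ancestry-condition line", {
  cfg <- simulation_config(lakes = tiny_lakes(), seed = 1)
  # Wr = 100 means the weight is exactly the standard weight
  cfg0 <- simulation_config(lakes = tiny_lakes(),
                            condition_slope = c(piscivorous = 0,
                                                planktivorous = 0),
                            condition_intercept = c(piscivorous = 100,
                                                    planktivorous = 100),
                            seed = 1)
  w <- assign_weight(400, 0.5, "planktivorous", cfg0)
  expect_equal(as.numeric(w), standard_weight(400), tolerance = 1e-12)
  # fully local planktivorous fish: 88.6 + 0.15 * 100
  w1 <- assign_weight(400, 1, "planktivorous", cfg)
  expect_equal(attr(w1, "wr_true"), 103.6, tolerance = 1e-12)
  # intercept case
  w0 <- assign_weight(400, 0, "planktivorous", cfg)
  expect_equal(attr(w0, "wr_true"), 88.6, tolerance = 1e-12)
  expect_error(assign_weight(-5, 1, "planktivorous", cfg), "TL")
})

test_that("invalid configurations fail naming the offending field", {
  om <- default_origin_mix()
  om$p_local[1] <- om$p_local[1] + 0.2
  expect_error(simulation_config(origin_mix = om), "origin_mix")
  vm <- default_vbgm_means()
  vm$k[2] <- -0.1
  expect_error(simulation_config(vbgm_means = vm), "vbgm_means\\$k")
  lk <- default_lakes()
  lk$n_fish[1] <- 0L
  expect_error(simulation_config(lakes = lk), "n_fish")
  qb <- default_q_beta()
  qb$shape1[1] <- 0
  expect_error(simulation_config(q_beta_params = qb), "q_beta_params")
  op <- default_otolith_power()
  op$v[1] <- -1
  expect_error(simulation_config(otolith_power = op), "otolith_power\\$v")
})

test_that("per-lake origin frequencies converge to the configured mix", {
  probs <- c(0.5, 0.3, 0.2)
  setup <- one_stocked_lake(10000L, mix = probs)
  cfg <- simulation_config(lakes = setup$lakes, origin_mix = setup$origin_mix,
                           seed = 17)
  co <- simulate_cohort(cfg)
  counts <- table(factor(co$truth$origin,
                         levels = c("local", "hybrid", "stocked")))
  gof <- stats::chisq.test(counts, p = probs)
  expect_gt(gof$p.value, 0.01)
})

test_that("simulated Wr regressed on percent local recovers the slope", {
  # cohort-level recovery: the configured ancestry slope lies in the fitted
  # regression's own 95% CI in at least 90% of seeds
  setup <- one_stocked_lake(160L)
  covered <- vapply(1:20, function(s) {
    cfg <- simulation_config(lakes = setup$lakes,
                             origin_mix = setup$origin_mix, seed = s)
    co <- simulate_cohort(cfg)
    reg <- regress_wr(100 * co$truth$q_local, co$truth$wr_true)
    ci <- confint(reg)
    ci["slope", 1] <= 0.15 && 0.15 <= ci["slope", 2]
  }, logical(1))
  expect_gte(sum(covered), 18)
})

test_that("direct experiment generators are seeded and on-line", {
  d1 <- simulate_wr_ancestry(50, 0.15, 88.6, sigma = 0, seed = 5)
  expect_equal(d1$wr, 88.6 + 0.15 * d1$pct_local, tolerance = 1e-12)
  d2 <- simulate_wr_ancestry(50, 0.15, 88.6, sigma = 8, seed = 5)
  d3 <- simulate_wr_ancestry(50, 0.15, 88.6, sigma = 8, seed = 5)
  expect_identical(d2, d3)
  la <- simulate_length_at_age(5, 464, 0.13, -0.43, measurement_cv = 0,
                               seed = 2)
  expect_equal(la$length_mm, 464 * (1 - exp(-0.13 * (la$age + 0.43))),
               tolerance = 1e-12)
  # sigma chosen from a target R2 lands near that R2 at large n
  sig <- wr_sigma_for_r2(0.15, c(0, 100), 0.22)
  d4 <- simulate_wr_ancestry(20000, 0.15, 88.6, sig, seed = 11)
  expect_equal(summary(stats::lm(wr ~ pct_local, d4))$adj.r.squared, 0.22,
               tolerance = 0.03)
})
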