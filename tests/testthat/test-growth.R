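test_that("power regression matches closed-form least squares", {
  # exact linear-in-log data
  S <- c(100, 250, 700, 1500)
  f <- fit_power_regression(S, 2 * S)
  expect_equal(f$u, 2, tolerance = 1e-10)
  expect_equal(f$v, 1, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-10)
  # three hand-chosen points: solve the 2x2 normal equations directly
  S3 <- c(100, 200, 400); L3 <- c(50, 120, 260)
  x <- log(S3); y <- log(L3)
  v_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  u_hand <- exp(mean(y) - v_hand * mean(x))
  f3 <- fit_power_regression(S3, L3)
  expect_equal(f3$v, v_hand, tolerance = 1e-12)
  expect_equal(f3$u, u_hand, tolerance = 1e-12)
  expect_error(fit_power_regression(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_power_regression(c(1, -2, 3), c(1, 2, 3)), "positive")
})

test_that("power regression recovers known generating coefficients", {
  set.seed(12)
  S <- stats::runif(300, 400, 3000)
  L <- 0.811 * S^0.85 * exp(stats::rnorm(300, 0, 0.05))
  f <- fit_power_regression(S, L)
  ct <- summary(f$fit)$coefficients
  expect_lt(abs(f$v - 0.85) / ct[2, 2], 3)
  expect_lt(abs(log(f$u) - log(0.811)) / ct[1, 2], 3)
})

test_that("slope homogeneity test behaves as an ANCOVA interaction F", {
  set.seed(4)
  S <- stats::runif(60, 400, 3000)
  L <- 0.5 * S^0.9 * exp(stats::rnorm(60, 0, 0.05))
  # identical groups duplicated: interaction is exactly zero
  st <- compare_slopes(c(S, S), c(L, L), rep(c("a", "b"), each = 60))
  expect_lt(st$statistic, 1e-16)
  expect_equal(st$p.value, 1, tolerance = 1e-8)
  expect_equal(st$df, c(1, 2 * 60 - 4))
  # single-df identity: F equals the squared interaction t statistic
  S2 <- stats::runif(50, 400, 3000)
  L2 <- 0.8 * S2^0.84 * exp(stats::rnorm(50, 0, 0.05))
  st2 <- compare_slopes(c(S, S2), c(L, L2), rep(c("a", "b"), c(60, 50)))
  fit <- stats::lm(log(c(L, L2)) ~ log(c(S, S2)) * rep(c("a", "b"), c(60, 50)))
  expect_equal(st2$statistic, summary(fit)$coefficients[4, "t value"]^2,
               tolerance = 1e-10)
  expect_error(compare_slopes(S, L, rep("a", 60)), "two")
})

test_that("clearly different exponents are detected", {
  hits <- vapply(1:20, function(s) {
    set.seed(100 + s)
    S <- stats::runif(80, 400, 3000)
    La <- 0.27 * S^1.03 * exp(stats::rnorm(80, 0, 0.05))
    Sb <- stats::runif(80, 400, 3000)
    Lb <- 0.811 * Sb^0.85 * exp(stats::rnorm(80, 0, 0.05))
    compare_slopes(c(S, Sb), c(La, Lb),
                   rep(c("pisc", "plank"), each = 80))$p.value < 0.01
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("ecotype-specific power regressions outfit the combined one", {
  set.seed(77)
  S <- stats::runif(150, 400, 3000)
  Sb <- stats::runif(150, 400, 3000)
  La <- 0.27 * S^1.03 * exp(stats::rnorm(150, 0, 0.05))
  Lb <- 0.811 * Sb^0.85 * exp(stats::rnorm(150, 0, 0.05))
  combined <- fit_power_regression(c(S, Sb), c(La, Lb))
  expect_gt(fit_power_regression(S, La)$r2, combined$r2)
  expect_gt(fit_power_regression(Sb, Lb)$r2, combined$r2)
})

test_that("BPH back-calculation matches direct evaluation", {
  expect_equal(back_calculate(400, 1000, 1000, v = 1.03), 400)  # S_i = S
  expect_equal(back_calculate(400, 1000, 500, v = 1), 200)
  expect_equal(back_calculate(400, 1000, 500, v = 1.03),
               400 * 0.5^1.03, tolerance = 1e-12)
  # identity at capture holds for any exponent
  for (v in c(0.5, 0.85, 1, 1.03, 2)) {
    expect_equal(back_calculate(412.3, 1530.5, 1530.5, v), 412.3)
  }
  expect_error(back_calculate(400, 1000, 1100, v = 1),
               class = "troutgrowth_monotonicity")
  expect_error(back_calculate(400, -1, 0.5, v = 1), "positive")
})

test_that("cohort back-calculation excludes non-monotonic fish", {
  cfg <- simulation_config(lakes = tiny_lakes(4L, 4L), seed = 8)
  co <- simulate_cohort(cfg)
  oto <- co$otoliths
  # corrupt one fish: make its first annulus larger than its capture radius
  fid <- co$fish$fish_id[1]
  cap <- oto$radius_um[oto$fish_id == fid & oto$is_capture_radius]
  oto$radius_um[oto$fish_id == fid & !oto$is_capture_radius][1] <- cap * 1.5
  expect_message(bc <- back_calculate_cohort(co$fish, oto), "non-monotonic")
  expect_equal(attr(bc, "excluded"), fid)
  expect_false(fid %in% bc$fish_id)
})

test_that("Ford-Walford starts are exact on noiseless curves", {
  ages <- 1:10
  L <- 500 * (1 - exp(-0.2 * (ages - 0)))
  st <- ford_walford_start(ages, L)
  expect_false(st$fallback)
  expect_equal(st$linf, 500, tolerance = 1e-6)
  expect_equal(st$k, 0.2, tolerance = 1e-6)
  expect_equal(st$t0, 0, tolerance = 1e-6)
})

test_that("Ford-Walford transforms the hand-computed Walford line", {
  ages <- 1:4
  L <- c(100, 180, 240, 290)
  x <- L[1:3]; y <- L[2:4]
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  st <- ford_walford_start(ages, L)
  expect_equal(st$k, -log(b), tolerance = 1e-12)
  expect_equal(st$linf, a / (1 - b), tolerance = 1e-12)
  linf <- a / (1 - b); k <- -log(b)
  t0_hand <- mean(ages + log(1 - L / linf) / k)
  expect_equal(st$t0, t0_hand, tolerance = 1e-12)
})

test_that("degenerate series engage the fallback starts", {
  st <- ford_walford_start(1:6, rep(300, 6))
  expect_true(st$fallback)
  expect_equal(st$linf, 1.1 * 300)
  st2 <- ford_walford_start(c(1, 3, 5), c(100, 200, 250))  # no consecutive ages
  expect_true(st2$fallback)
})

test_that("the VBGM fit recovers noiseless parameters exactly", {
  ages <- 1:15
  L <- 464 * (1 - exp(-0.13 * (ages + 0.43)))
  fit <- fit_vbgm(ages, L)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), c(464, 0.13, -0.43), tolerance = 1e-5)
  expect_equal(fit$omega, 464 * 0.13, tolerance = 1e-4)
  expect_error(fit_vbgm(1:3, L[1:3]), "4 distinct ages")
})

test_that("the VBGM fit recovers noisy parameters within bootstrap error", {
  set.seed(21)
  ages <- 1:20
  L <- 500 * (1 - exp(-0.2 * ages)) + stats::rnorm(20, 0, 5)
  fit <- fit_vbgm(ages, L, boot_reps = 199, seed = 22)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["linf"]] - 500) / fit$se[["linf"]], 3)
  expect_lt(abs(coef(fit)[["k"]] - 0.2) / fit$se[["k"]], 3)
})

test_that("bootstrap SEs are reproducible, degenerate at zero noise, and shrink with n", {
  ages <- 1:12
  L <- 464 * (1 - exp(-0.13 * (ages + 0.43)))
  f1 <- fit_vbgm(ages, L, boot_reps = 99, seed = 5)
  f2 <- fit_vbgm(ages, L, boot_reps = 99, seed = 5)
  expect_identical(f1$se, f2$se)
  expect_lt(f1$se[["linf"]], 1e-3 * coef(f1)[["linf"]])
  expect_lt(f1$se[["k"]], 1e-3 * coef(f1)[["k"]])
  # quadrupling the observations roughly halves the SE on average over
  # replicate datasets (single realizations are too noisy to compare)
  ratios <- vapply(1:6, function(s) {
    set.seed(330 + s)
    mk <- function(reps) {
      a <- rep(1:20, reps)
      data.frame(age = a, L = 500 * (1 - exp(-0.2 * a)) +
                   stats::rnorm(length(a), 0, 8))
    }
    d1 <- mk(2); d4 <- mk(8)
    fit_vbgm(d1$age, d1$L, boot_reps = 199, seed = 1000 + s)$se[["linf"]] /
      fit_vbgm(d4$age, d4$L, boot_reps = 199, seed = 2000 + s)$se[["linf"]]
  }, numeric(1))
  expect_gt(mean(ratios), 1.5)
  expect_lt(mean(ratios), 2.8)
})

test_that("the relative-SE filter removes exactly the poor fits", {
  # boundary: both ratios exactly at the threshold are retained
  fits <- data.frame(id = c("a", "b", "c"),
                     linf = c(500, 500, 500), k = c(0.2, 0.2, 0.2),
                     t0 = 0, se_linf = c(125, 150, 10),
                     se_k = c(0.05, 0.01, 0.06), se_t0 = 0.1,
                     omega = 100, n_points = 10, converged = TRUE)
  out <- suppressMessages(filter_fits(fits))
  expect_equal(out$retained, c(TRUE, FALSE, FALSE))
  # constructed cohort with 17 planted bad fits among 196
  set.seed(55)
  n <- 196
  good <- data.frame(id = sprintf("g%03d", 1:n), linf = 500, k = 0.2, t0 = 0,
                     se_linf = stats::runif(n, 5, 100),
                     se_k = stats::runif(n, 0.005, 0.045),
                     se_t0 = 0.1, omega = 100, n_points = 10,
                     converged = TRUE)
  bad_idx <- sample(n, 17)
  good$se_linf[bad_idx] <- 500 * stats::runif(17, 0.26, 0.6)
  out2 <- suppressMessages(filter_fits(good))
  expect_equal(sum(!out2$retained), 17)
  expect_equal(sort(which(!out2$retained)), sort(bad_idx))
})

test_that("omega is the analytic slope of the growth curve at t0", {
  expect_equal(omega(464, 0.13), 60.32)
  expect_equal(omega(500, 0), 0)
  ages <- 1:15
  L <- 620 * (1 - exp(-0.11 * (ages - 0.2)))
  fit <- fit_vbgm(ages, L)
  t0 <- coef(fit)[["t0"]]; h <- 1e-6
  slope_num <- (predict(fit, t0 + h) - predict(fit, t0 - h)) / (2 * h)
  expect_equal(slope_num, fit$omega, tolerance = 1e-6)
})

test_that("omega is invariant to an additive age shift", {
  set.seed(60)
  ages <- rep(1:15, 2)
  L <- 464 * (1 - exp(-0.13 * (ages + 0.43))) + stats::rnorm(30, 0, 4)
  f0 <- fit_vbgm(ages, L)
  f5 <- fit_vbgm(ages + 5, L)
  expect_equal(f5$omega, f0$omega, tolerance = 1e-4)
  expect_equal(coef(f5)[["t0"]], coef(f0)[["t0"]] + 5, tolerance = 1e-3)
})

test_that("vbgm_fit methods are coherent", {
  ages <- 1:12
  L <- 464 * (1 - exp(-0.13 * (ages + 0.43)))
  fit <- fit_vbgm(ages, L)
  expect_named(coef(fit), c("linf", "k", "t0"))
  expect_equal(predict(fit, coef(fit)[["t0"]]), 0, tolerance = 1e-8)
  expect_equal(fitted(fit) + residuals(fit), L, tolerance = 1e-8)
  expect_output(print(fit), "Von Bertalanffy")
  expect_output(print(summary(fit)), "omega")
  tab <- vbgm_table(list(a = fit))
  expect_equal(tab$linf, coef(fit)[["linf"]])
  expect_true(tab$converged)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
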