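# Small design used where the full survey scale is not needed.
tiny_lakes <- function(n_unstocked = 8L, n_stocked = 15L) {
  lk <- default_lakes()
  lk$n_fish <- ifelse(lk$stocked, n_stocked, n_unstocked)
  lk
}

# One stocked planktivorous lake, configurable size.
one_stocked_lake <- function(n, ecotype = "planktivorous",
                             mix = c(0.4, 0.35, 0.25)) {
  lakes <- data.frame(name = "TestLake", ecotype = ecotype, stocked = TRUE,
                      n_fish = as.integer(n), n_sources = 1L,
                      stringsAsFactors = FALSE)
  origin_mix <- data.frame(lake = "TestLake", p_local = mix[1],
                           p_hybrid = mix[2], p_stocked = mix[3])
  list(lakes = lakes, origin_mix = origin_mix)
}

# Balanced multi-lake phenotype table for mixed-model tests: a known fixed
# structure plus lake random intercepts and residual noise.
sim_mixed_data <- function(n_lakes = 10, n_per_lake = 30, eco_effect = 0,
                           lake_sd = 10, resid_sd = 50, intercept = 500,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lakes <- sprintf("L%02d", seq_len(n_lakes))
  eco <- rep(c("piscivorous", "planktivorous"), length.out = n_lakes)
  stocked <- rep(c(TRUE, FALSE), each = ceiling(n_lakes / 2),
                 length.out = n_lakes)
  u <- stats::rnorm(n_lakes, 0, lake_sd)
  d <- do.call(rbind, lapply(seq_len(n_lakes), function(i) {
    data.frame(lake = lakes[i], ecotype = eco[i], stocked = stocked[i],
               sex = sample(c("female", "male"), n_per_lake, replace = TRUE),
               y = intercept + eco_effect * (eco[i] == "planktivorous") +
                 u[i] + stats::rnorm(n_per_lake, 0, resid_sd),
               stringsAsFactors = FALSE)
  }))
  d
}
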