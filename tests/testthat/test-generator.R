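test_that("default designs enumerate the study cohorts exactly", {
  cfg <- generator_config()
  resp <- build_cohort(cfg, seed = 11)
  expect_equal(nrow(resp), 158)
  counts <- table(resp$population, resp$acclimation_temp)
  expect_equal(counts["Myrt Lake", "8"], 9)
  expect_equal(counts["Myrt Lake", "11"], 9)
  expect_equal(sum(counts == 10), 14)
  ctm <- build_cohort(cfg, seed = 11, design = "ctm")
  expect_equal(nrow(ctm), 160)
  expect_true(all(table(ctm$population, ctm$acclimation_temp) == 10))
  # cell counts equal the configured counts exactly, whatever they are
  cfg2 <- quick_config()
  co2 <- build_cohort(cfg2, seed = 3)
  expect_true(all(table(co2$population, co2$acclimation_temp) == 6))
})

test_that("invalid configurations are rejected with a named field", {
  expect_error(generator_config(n_per_cell_ctm = 0),
               class = "troutherm_config_error")
  expect_error(generator_config(ramp_rate = 0), class = "troutherm_config_error")
  expect_error(generator_config(mmr_ref = c(`8` = 1, `11` = 1, `15` = 1, `19` = 1)),
               regexp = "mmr_ref", class = "troutherm_config_error")
  expect_error(generator_config(recovery_log_slope_by_acclimation =
                                  c(`8` = 2, `11` = -1, `15` = -1, `19` = -1)),
               class = "troutherm_config_error")
})

test_that("generators are bit-identical for identical config and seed", {
  cfg <- quick_config()
  expect_identical(build_cohort(cfg, seed = 7), build_cohort(cfg, seed = 7))
  f <- test_fish()
  expect_identical(simulate_closed_trace(5, f, cfg, seed = 7),
                   simulate_closed_trace(5, f, cfg, seed = 7))
  expect_identical(simulate_recovery_series(f, 40, cfg, seed = 7, beta1 = -5),
                   simulate_recovery_series(f, 40, cfg, seed = 7, beta1 = -5))
  co <- build_cohort(cfg, seed = 7, design = "ctm")
  expect_identical(simulate_ctm_cohort(co, cfg, seed = 7),
                   simulate_ctm_cohort(co, cfg, seed = 7))
})

test_that("closed traces invert the oxygen-consumption formula", {
  cfg <- generator_config(trace_noise_sd = 0, background_slope = 0)
  f <- test_fish(mass_g = 100) # Vm = 0.1 l in a 1.1 l chamber
  tr <- simulate_closed_trace(3.0, f, cfg, seed = 1)
  rate <- -coef(lm(o2_mg_per_l ~ time_min, tr$samples))[[2]]
  expect_equal(rate, 0.05, tolerance = 1e-12)
  # a null fish yields a constant series
  tr0 <- simulate_closed_trace(0, f, cfg, seed = 1)
  expect_equal(diff(range(tr0$samples$o2_mg_per_l)), 0)
  # oversized fish cannot fit the chamber
  expect_error(simulate_closed_trace(3, test_fish(mass_g = 1200), cfg),
               class = "troutherm_geometry_error")
  expect_error(simulate_closed_trace(-1, f, cfg),
               class = "troutherm_parameter_error")
})

test_that("recovery series follow the configured logarithmic decline", {
  cfg <- generator_config(recovery_cv = 0)
  f <- test_fish()
  flat <- simulate_recovery_series(f, 40, cfg, seed = 1, beta1 = 0)
  expect_equal(flat$measurements$mo2_mg_per_h, rep(40, 8))
  # schedule: eight 5-min windows with 5-min flushes spanning 75 min
  expect_equal(flat$measurements$midpoint_min, seq(2.5, 72.5, by = 10))
  rs <- simulate_recovery_series(f, 40, cfg, seed = 1, beta1 = -5)
  expect_equal(rs$measurements$mo2_mg_per_h[1], 40 - 5 * log(2.5), tolerance = 1e-12)
  # floor keeps late recovery from undershooting rest
  rs2 <- simulate_recovery_series(f, 40, cfg, seed = 1, beta1 = -9, rmr_floor = 6)
  expect_true(all(rs2$measurements$mo2_mg_per_h >= 6))
  expect_error(simulate_recovery_series(f, 0, cfg),
               class = "troutherm_parameter_error")
})

test_that("CTM trials place loss of equilibrium on the ramp", {
  cfg <- generator_config(ctm_sd = 0)
  co <- build_cohort(cfg, seed = 5, design = "ctm")
  trials <- simulate_ctm_cohort(co, cfg, seed = 5)
  vals <- ctm_values_all(trials)
  merged <- merge(co, vals, by = "fish_id")
  # degenerate noise: every fish sits exactly at its configured cell mean
  for (temp in c(8, 11, 15, 19)) {
    expect_equal(unique(merged$ctm_C[merged$acclimation_temp == temp]),
                 unname(cfg$ctm_mean_by_acclimation[as.character(temp)]),
                 tolerance = 1e-12)
  }
  # trial start temperatures equal the acclimation temperature
  starts <- vapply(trials, function(tr) tr$ramp$start_temp, numeric(1))
  expect_setequal(unique(starts), c(8, 11, 15, 19))
})

test_that("generated true metabolic rates carry the configured allometry", {
  cfg <- generator_config()
  co <- build_cohort(cfg, seed = 2)
  truth <- true_metabolic_rates(co, cfg, seed = 2, biological_noise = FALSE)
  # noise-free truth is an exact power law of mass within each temperature
  fit <- lm(log10(rmr_true) ~ log10(mass_g) + factor(acclimation_temp), truth)
  expect_equal(coef(fit)[["log10(mass_g)"]], 1.12, tolerance = 1e-10)
  sub <- truth[truth$population != "Lake Manitou", ]
  fitm <- lm(log10(mmr_true) ~ log10(mass_g) + factor(acclimation_temp), sub)
  expect_equal(coef(fitm)[["log10(mass_g)"]], 0.82, tolerance = 1e-10)
  expect_true(all(truth$mmr_true > truth$rmr_true))
})

test_that("Monte-Carlo calibration recovers the configured anchors", {
  cfg <- generator_config()
  seeds <- 1:20
  ctm8 <- numeric(length(seeds))
  rmr_norm <- mmr_norm <- matrix(NA_real_, length(seeds), 4,
                                 dimnames = list(NULL, c("8", "11", "15", "19")))
  for (i in seq_along(seeds)) {
    co <- build_cohort(cfg, seed = seeds[i], design = "ctm")
    vals <- ctm_values_all(simulate_ctm_cohort(co, cfg, seed = seeds[i]))
    m <- merge(co, vals, by = "fish_id")
    ctm8[i] <- mean(m$ctm_C[m$acclimation_temp == 8])
    resp <- true_metabolic_rates(build_cohort(cfg, seed = seeds[i]), cfg,
                                 seed = seeds[i])
    rel <- resp$mass_g / cfg$reference_mass
    for (tt in colnames(rmr_norm)) {
      sel <- resp$acclimation_temp == as.numeric(tt)
      rmr_norm[i, tt] <- mean(resp$rmr_true[sel] / rel[sel]^cfg$rmr_mass_exponent)
      selp <- sel & resp$population != "Lake Manitou"
      mmr_norm[i, tt] <- mean(resp$mmr_true[selp] / rel[selp]^cfg$mmr_mass_exponent)
    }
  }
  # grand-mean CTM at 8 C acclimation sits in the calibrated band
  expect_gt(mean(ctm8), 26.0)
  expect_lt(mean(ctm8), 26.2)
  # cell means of mass-normalised rates recover the anchors within 3 MC SE
  for (tt in colnames(rmr_norm)) {
    mc_se <- sd(rmr_norm[, tt]) / sqrt(length(seeds))
    expect_lt(abs(mean(rmr_norm[, tt]) - cfg$rmr_ref[[tt]]), 3 * mc_se + 1e-9)
    mc_se_m <- sd(mmr_norm[, tt]) / sqrt(length(seeds))
    expect_lt(abs(mean(mmr_norm[, tt]) - cfg$mmr_ref[[tt]]), 3 * mc_se_m + 1e-9)
  }
})
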