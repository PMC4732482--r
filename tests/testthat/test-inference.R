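test_that("Fulton's condition factor reproduces the reference values", {
  expect_equal(round(condition_factor(116.9, 20.7), 1), 1.3)
  expect_equal(round(condition_factor(84.1, 19.1), 1), 1.2)
  expect_equal(condition_factor(100, 10), 10)
  expect_error(condition_factor(-1, 10), class = "troutherm_domain_error")
  expect_error(condition_factor(10, 0), class = "troutherm_domain_error")
})

test_that("factorial ANOVA/ANCOVA reproduce the study's residual df", {
  cfg <- generator_config()
  ctm_cohort <- build_cohort(cfg, seed = 21, design = "ctm")
  vals <- ctm_values_all(simulate_ctm_cohort(ctm_cohort, cfg, seed = 21))
  ctm_data <- merge(ctm_cohort, vals, by = "fish_id")
  fit <- two_way_anova(ctm_data, "ctm_C")
  expect_equal(fit$table$df[fit$table$term == "Residuals"], 144)

  resp <- true_metabolic_rates(build_cohort(cfg, seed = 21), cfg, seed = 21)
  afit <- two_way_ancova(resp, "rmr_true")
  expect_equal(afit$table$df[afit$table$term == "Residuals"], 141)

  # toy count: 2x2 with 2 per cell leaves 4 residual df
  toy <- data.frame(population = rep(c("a", "b"), each = 4),
                    acclimation_temp = rep(c(8, 19), 4),
                    y = rnorm(8))
  tfit <- two_way_anova(toy, "y")
  expect_equal(tfit$table$df[tfit$table$term == "Residuals"], 4)
})

test_that("balanced ANOVA matches the explicit cell-mean decomposition", {
  set.seed(31)
  d <- expand.grid(population = c("p1", "p2", "p3"),
                   acclimation_temp = c(8, 11, 15, 19))
  d <- d[rep(seq_len(nrow(d)), each = 5), ]
  d$y <- 2 + 0.5 * as.numeric(factor(d$population)) +
    0.1 * d$acclimation_temp + rnorm(nrow(d), 0, 0.7)
  fit <- two_way_anova(d, "y")
  oracle <- twoway_ss_oracle(d$y, d$population, d$acclimation_temp)
  tab <- fit$table
  ss <- function(term) tab$sum_sq[tab$term == term]
  expect_equal(ss("population"), oracle$ss_a, tolerance = 1e-9)
  expect_equal(ss("acclimation_temp"), oracle$ss_b, tolerance = 1e-9)
  expect_equal(ss("population:acclimation_temp"), oracle$ss_ab, tolerance = 1e-9)
  expect_equal(ss("Residuals"), oracle$ss_e, tolerance = 1e-9)
  # SS conservation
  expect_equal(sum(tab$sum_sq), oracle$ss_total, tolerance = 1e-9)
  # Type III agrees on this balanced design
  fit3 <- two_way_anova(d, "y", ss_type = "III")
  expect_equal(fit3$table$sum_sq[fit3$table$term == "population"],
               oracle$ss_a, tolerance = 1e-9)
})

test_that("an exact power law is captured entirely by the covariate", {
  set.seed(5)
  d <- expand.grid(population = c("p1", "p2"), acclimation_temp = c(8, 19))
  d <- d[rep(seq_len(nrow(d)), each = 10), ]
  d$mass_g <- exp(rnorm(nrow(d), log(100), 0.2))
  d$y <- 2.5 * d$mass_g^0.82
  fit <- suppressWarnings(two_way_ancova(d, "y")) # perfect fit by design
  expect_equal(unname(fit$covariate_slope["estimate"]), 0.82, tolerance = 1e-10)
  tab <- fit$table
  expect_lt(tab$sum_sq[tab$term == "population"], 1e-12)
  expect_lt(tab$sum_sq[tab$term == "acclimation_temp"], 1e-12)
  expect_error(two_way_ancova(transform(d, mass_g = 100), "y"),
               class = "troutherm_rank_error")
})

test_that("a factor-orthogonal covariate leaves the factor SS unchanged", {
  set.seed(6)
  d <- expand.grid(population = c("p1", "p2"), acclimation_temp = c(8, 11, 15))
  d <- d[rep(seq_len(nrow(d)), each = 8), ]
  d <- d[order(d$population, d$acclimation_temp), ]
  d$y <- 1 + 0.4 * (d$population == "p2") + 0.05 * d$acclimation_temp +
    rnorm(nrow(d), 0, 0.2)
  # identical mean mass in every cell: the covariate is exactly orthogonal
  # to the factor space, so the sequential factor SS must not move
  d$mass_g <- 100 + rep(c(-5, 5), nrow(d) / 2)
  a <- two_way_anova(d, "y")
  b <- two_way_ancova(d, "y", log10_response = FALSE, log10_covariate = FALSE)
  for (trm in c("population", "acclimation_temp")) {
    expect_equal(b$table$sum_sq[b$table$term == trm],
                 a$table$sum_sq[a$table$term == trm], tolerance = 1e-9)
  }
})

test_that("homogeneity-of-slopes flags heterogeneous cells and guards df", {
  set.seed(8)
  d <- expand.grid(population = c("p1", "p2"), acclimation_temp = c(8, 19))
  d <- d[rep(seq_len(nrow(d)), each = 50), ]
  d$mass_g <- runif(nrow(d), 80, 140)
  slope <- ifelse(d$population == "p2" & d$acclimation_temp == 19, 1.6, 0.8)
  d$y <- 10^(0.1 + slope * log10(d$mass_g) + rnorm(nrow(d), 0, 0.02))
  het <- homogeneity_of_slopes(d, "y")
  expect_lt(het$p, 0.001)
  # common slope: no rejection on this draw
  d$y <- 10^(0.1 + 0.8 * log10(d$mass_g) + rnorm(nrow(d), 0, 0.02))
  hom <- homogeneity_of_slopes(d, "y")
  expect_gt(hom$p, 0.001)
  single <- d[d$population == "p1" & d$acclimation_temp == 8, ]
  expect_error(homogeneity_of_slopes(single, "y"),
               class = "troutherm_design_error")
})

test_that("adjusted means match the closed-form normal-equation oracle", {
  set.seed(12)
  d <- expand.grid(population = c("g1", "g2"), acclimation_temp = c(8, 11, 15))
  d <- d[rep(seq_len(nrow(d)), each = 4), ]
  d$mass_g <- runif(nrow(d), 90, 130)
  d$y <- 3 + 0.6 * (d$population == "g2") - 0.02 * as.numeric(factor(d$acclimation_temp)) +
    0.01 * d$mass_g + rnorm(nrow(d), 0, 0.1)
  fit <- two_way_ancova(d, "y", log10_response = FALSE, log10_covariate = FALSE)
  x0 <- 108.6
  # cell-means coding solved by explicit normal equations
  cell <- interaction(d$population, d$acclimation_temp, drop = TRUE)
  X <- cbind(stats::model.matrix(~ cell - 1), x = d$mass_g)
  beta <- solve(crossprod(X), crossprod(X, d$y))
  mu <- beta[seq_len(nlevels(cell))]
  names(mu) <- levels(cell)
  b <- beta[length(beta)]
  for (g in c("g1", "g2")) {
    oracle <- mean(mu[grep(paste0("^", g, "\\."), names(mu))]) + b * x0
    am <- suppressMessages(adjusted_means(fit, "population", reference_mass = x0))
    expect_equal(am$ls_mean[am$group == g], unname(oracle), tolerance = 1e-9)
  }
})

test_that("adjusted means reduce to raw means when no adjustment is needed", {
  set.seed(13)
  d <- expand.grid(population = c("g1", "g2"), acclimation_temp = c(8, 19))
  d <- d[rep(seq_len(nrow(d)), each = 6), ]
  # covariate symmetric about the reference in every cell: group means sit
  # exactly at the reference mass, so adjustment is a no-op
  d$mass_g <- 108.6 + rep(c(-5, 5), nrow(d) / 2)
  d$y <- 2 + 0.5 * (d$acclimation_temp == 19) + rnorm(nrow(d), 0, 0.3)
  fit <- two_way_ancova(d, "y", log10_response = FALSE, log10_covariate = FALSE)
  am <- suppressMessages(adjusted_means(fit, "acclimation_temp", reference_mass = 108.6))
  raw <- tapply(d$y, d$acclimation_temp, mean)
  expect_equal(am$ls_mean, as.numeric(raw[am$group]), tolerance = 1e-9)
  # ANOVA-layer means with no covariate are the raw group means
  afit <- two_way_anova(d, "y")
  am2 <- suppressMessages(adjusted_means(afit, "acclimation_temp"))
  expect_equal(am2$ls_mean, as.numeric(raw[am2$group]), tolerance = 1e-12)
  # warning when the reference lies outside the observed masses
  expect_warning(adjusted_means(fit, "population", reference_mass = 500),
                 regexp = "outside")
})

test_that("adjusted means are invariant to recentring the covariate", {
  set.seed(14)
  d <- expand.grid(population = c("g1", "g2"), acclimation_temp = c(8, 19))
  d <- d[rep(seq_len(nrow(d)), each = 5), ]
  d$mass_g <- runif(nrow(d), 90, 130)
  d$y <- 1 + 0.01 * d$mass_g + 0.3 * (d$population == "g2") + rnorm(nrow(d), 0, 0.1)
  f1 <- two_way_ancova(d, "y", log10_response = FALSE, log10_covariate = FALSE)
  d2 <- transform(d, mass_g = mass_g - 50)
  f2 <- two_way_ancova(d2, "y", log10_response = FALSE, log10_covariate = FALSE)
  a1 <- suppressMessages(adjusted_means(f1, "population", reference_mass = 110))
  a2 <- suppressMessages(adjusted_means(f2, "population", reference_mass = 60))
  expect_equal(a1$ls_mean, a2$ls_mean, tolerance = 1e-9)
  expect_equal(a1$sem, a2$sem, tolerance = 1e-9)
})

test_that("mass exponents recover exact scaling relations", {
  set.seed(15)
  d <- expand.grid(population = c("g1", "g2"), acclimation_temp = c(8, 19))
  d <- d[rep(seq_len(nrow(d)), each = 8), ]
  d$mass_g <- exp(rnorm(nrow(d), log(110), 0.15))
  d$y <- d$mass_g
  expect_equal(suppressWarnings(mass_exponent(d, "y"))$exponent, 1,
               tolerance = 1e-10) # noise-free fits warn about perfection
  d$y <- 3 * d$mass_g^0.82
  expect_equal(suppressWarnings(mass_exponent(d, "y"))$exponent, 0.82,
               tolerance = 1e-10)
  expect_equal(suppressWarnings(mass_exponent(d, "y", method = "pooled"))$exponent,
               0.82, tolerance = 1e-10)
  d$y[1] <- -1
  expect_error(mass_exponent(d, "y"), class = "troutherm_domain_error")
})

test_that("Tukey HSD agrees with the pooled t-test for two groups", {
  set.seed(16)
  d <- data.frame(g = rep(c("a", "b"), each = 12), y = rnorm(24))
  d$y[d$g == "b"] <- d$y[d$g == "b"] + 0.8
  fit <- lm(y ~ g, data = d)
  tk <- tukey_hsd(fit, "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(tk$adjusted_p, tt$p.value, tolerance = 1e-10)
  expect_equal(tk$q_statistic, abs(tt$statistic[[1]]) * sqrt(2), tolerance = 1e-10)
  expect_equal(tk$difference, -diff(tapply(d$y, d$g, mean))[[1]], tolerance = 1e-10)
})

test_that("Tukey HSD separates shifted groups and respects monotonicity", {
  set.seed(17)
  resid <- rnorm(15, 0, 1)
  d <- data.frame(g = rep(c("a", "b", "c", "d"), each = 15),
                  y = rep(c(0, 0, 0, 10), each = 15) + rep(resid, 4))
  tk <- tukey_hsd(lm(y ~ g, data = d), "g")
  far <- tk$group_a == "d" | tk$group_b == "d"
  expect_true(all(tk$adjusted_p[far] < 0.001))
  expect_true(all(tk$adjusted_p[!far] > 0.99))
  # identical means: all adjusted p ~ 1
  d0 <- data.frame(g = rep(c("a", "b", "c"), each = 15), y = rep(resid, 3))
  tk0 <- tukey_hsd(lm(y ~ g, data = d0), "g")
  expect_true(all(tk0$adjusted_p > 0.999))
  # p nonincreasing in |difference| at fixed variance and df
  shifts <- c(0.2, 0.5, 1, 2)
  ps <- vapply(shifts, function(s) {
    dd <- data.frame(g = rep(c("a", "b"), each = 15),
                     y = c(resid, resid + s))
    tukey_hsd(lm(y ~ g, dd), "g")$adjusted_p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(tukey_hsd(lm(y ~ 1, data = d), "g"))
})

test_that("degenerate factorial inputs raise design errors", {
  d <- data.frame(population = "only", acclimation_temp = c(8, 19), y = c(1, 2))
  expect_error(two_way_anova(d, "y"), class = "troutherm_design_error")
  d2 <- data.frame(population = c("a", "a", "b"),
                   acclimation_temp = c(8, 19, 8), y = 1:3)
  expect_error(two_way_anova(d2, "y"), regexp = "empty design cell",
               class = "troutherm_design_error")
})
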