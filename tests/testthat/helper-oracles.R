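# Independent oracles used across the suite: explicit sum-formula OLS,
# the cell-mean two-way SS decomposition, and a small fast design.

# OLS by the raw normal-equation sums, no lm() involved.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x^2)
  b <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  a <- (sy - b * sx) / n
  resid <- y - a - b * x
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(intercept = a, slope = b, r_squared = r2)
}

# Balanced two-way ANOVA sums of squares by explicit cell-mean summation.
twoway_ss_oracle <- function(y, A, B) {
  A <- as.character(A); B <- as.character(B)
  grand <- mean(y)
  a_means <- tapply(y, A, mean)
  b_means <- tapply(y, B, mean)
  cell_means <- tapply(y, list(A, B), mean)
  n_cell <- table(A, B)
  stopifnot(length(unique(n_cell)) == 1) # balanced only
  n <- n_cell[1, 1]
  a <- length(a_means); b <- length(b_means)
  ss_a <- b * n * sum((a_means - grand)^2)
  ss_b <- a * n * sum((b_means - grand)^2)
  ss_ab <- n * sum((sweep(sweep(cell_means, 1, a_means - grand), 2, b_means - grand) - grand)^2)
  fitted_cell <- cell_means[cbind(A, B)]
  ss_e <- sum((y - fitted_cell)^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab, ss_e = ss_e,
       ss_total = sum((y - grand)^2))
}

# Compact 2 populations x 2 temperatures design for fast property tests.
quick_config <- function(...) {
  generator_config(
    populations = c("Myrt Lake", "Lake Manitou"),
    acclimation_temps = c(8, 19),
    n_per_cell_respirometry = 6,
    n_per_cell_ctm = 6,
    ...)
}

# One-row fish record for unit tests of the trace/recovery simulators.
test_fish <- function(mass_g = 100, temp = 8, pop = "Myrt Lake", id = "f1") {
  data.frame(fish_id = id, population = pop, acclimation_temp = temp,
             mass_g = mass_g, fork_length_cm = (100 * mass_g / 1.2)^(1 / 3),
             tank = "T8a", stringsAsFactors = FALSE)
}
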