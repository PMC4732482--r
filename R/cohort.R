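#' Generate a cohort of fish for one experimental design
#'
#' Draws one fish record per design cell per configured count. Body masses
#' are lognormal around the cell mean with CV `mass_cv`; fork length is
#' derived by inverting Fulton's condition factor, L = (100 M / K)^(1/3)
#' (M in g, L in cm), times small multiplicative noise, so generated cells
#' reproduce the configured condition-factor targets. Fish are assigned
#' alternately to the two replicate acclimation tanks of their temperature.
#'
#' @param config A [generator_config()] object.
#' @param seed Integer seed (NULL consumes the current RNG stream).
#' @param design `"respirometry"` or `"ctm"`: which per-cell counts, mass
#'   means and condition targets to use.
#' @return A data frame with one row per fish: `fish_id`, `population`,
#'   `acclimation_temp`, `mass_g`, `fork_length_cm`, `tank`.
#' @export
build_cohort <- function(config, seed = NULL, design = c("respirometry", "ctm")) {
  design <- match.arg(design)
  validate_config(config)
  n_tab <- if (design == "respirometry") config$n_per_cell_respirometry else config$n_per_cell_ctm
  mass_tab <- config$mass_mean_by_cell[[design]]
  k_tab <- config$condition_k_by_cell[[design]]

  with_seed(seed, {
    rows <- vector("list", nrow(n_tab))
    counter <- 0L
    prefix <- if (design == "respirometry") "R" else "C"
    for (i in seq_len(nrow(n_tab))) {
      pop <- n_tab$population[i]
      temp <- n_tab$acclimation_temp[i]
      n <- n_tab$n[i]
      cell_mass <- cell_value(mass_tab, pop, temp, "mass_g")
      cell_k <- cell_value(k_tab, pop, temp, "k")
      mp <- lnorm_pars(cell_mass, config$mass_cv)
      mass <- stats::rlnorm(n, mp$meanlog, mp$sdlog)
      len_noise <- stats::rlnorm(n, -log(1 + config$length_cv^2) / 2,
                                 sqrt(log(1 + config$length_cv^2)))
      fork_length <- (100 * mass / cell_k)^(1 / 3) * len_noise
      ids <- sprintf("%s%03d", prefix, counter + seq_len(n))
      counter <- counter + n
      rows[[i]] <- data.frame(
        fish_id = ids,
        population = pop,
        acclimation_temp = temp,
        mass_g = mass,
        fork_length_cm = fork_length,
        tank = sprintf("T%g%s", temp, rep_len(c("a", "b"), n)),
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

cell_value <- function(tab, pop, temp, col) {
  hit <- tab$population == pop & tab$acclimation_temp == temp
  if (!any(hit)) config_error(sprintf(
    "%s: no entry for cell (%s, %g)", col, pop, temp))
  tab[[col]][which(hit)[1]]
}

#' True (latent) metabolic rates for a generated cohort
#'
#' Computes each fish's true whole-animal RMR and MMR from the configured
#' anchors via the allometric model
#' `rate = ref(temp) * pop_effect * (mass / reference_mass)^b`, optionally
#' multiplied by lognormal between-fish biological scatter, plus the true
#' recovery-curve slope for its design cell. With `biological_noise =
#' FALSE` the rates are an exact power law of mass, so a log-log regression
#' recovers the configured exponent to machine precision.
#'
#' @param cohort Data frame from [build_cohort()].
#' @param config A [generator_config()].
#' @param seed Integer seed (NULL consumes the current stream).
#' @param biological_noise Draw between-fish lognormal deviates (default TRUE).
#' @return The cohort with columns `rmr_true`, `mmr_true`,
#'   `recovery_slope_true` (mg O2 h^-1; slope per ln-minute) appended.
#' @export
true_metabolic_rates <- function(cohort, config, seed = NULL, biological_noise = TRUE) {
  validate_config(config)
  tkey <- as.character(cohort$acclimation_temp)
  rel_mass <- cohort$mass_g / config$reference_mass
  with_seed(seed, {
    n <- nrow(cohort)
    eps_r <- if (biological_noise && config$rmr_cv > 0) {
      p <- lnorm_pars(1, config$rmr_cv); stats::rlnorm(n, p$meanlog, p$sdlog)
    } else rep(1, n)
    eps_m <- if (biological_noise && config$mmr_cv > 0) {
      p <- lnorm_pars(1, config$mmr_cv); stats::rlnorm(n, p$meanlog, p$sdlog)
    } else rep(1, n)
    rmr <- config$rmr_ref[tkey] * rel_mass^config$rmr_mass_exponent * eps_r
    mmr <- config$mmr_ref[tkey] * config$mmr_pop_multiplier[cohort$population] *
      rel_mass^config$mmr_mass_exponent * eps_m
    # keep exercised rate above rest even under extreme deviates
    mmr <- pmax(mmr, rmr * 1.05)
    cohort$rmr_true <- unname(rmr)
    cohort$mmr_true <- unname(mmr)
    cohort$recovery_slope_true <- unname(
      config$recovery_log_slope_by_acclimation[tkey] +
        config$recovery_slope_pop_shift[cohort$population])
    cohort
  })
}
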