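#' Configuration for the synthetic acclimation-experiment generator
#'
#' Builds the parameter set that drives every simulation: the factorial
#' design (four hatchery-reared lake trout populations crossed with four
#' acclimation temperatures), body-size distributions per design cell,
#' whole-animal metabolic-rate anchors at a reference mass, allometric mass
#' exponents, the post-exercise recovery curve, critical thermal maximum
#' (CTmax) means per acclimation temperature, and the measurement-noise
#' model for closed-chamber oxygen traces.
#'
#' Metabolic anchors (`rmr_ref`, `mmr_ref`) are whole-animal rates
#' (mg O2 h^-1) that a fish of exactly `reference_mass` grams would show;
#' individual fish scale as `ref * (mass/reference_mass)^exponent` times a
#' lognormal between-fish deviate with coefficient of variation `rmr_cv`
#' (resp. `mmr_cv`). Metabolic scope is emergent (MMR minus RMR per fish),
#' not separately parameterised.
#'
#' @param populations Character vector of population labels (default the
#'   four study lakes).
#' @param acclimation_temps Numeric acclimation temperatures in degrees C.
#' @param n_per_cell_respirometry Either a single count or a data frame with
#'   columns `population`, `acclimation_temp`, `n`. The default reproduces
#'   the study's respirometry sample sizes: 10 fish per cell except the
#'   Myrt Lake cells at 8 and 11 degrees C with 9, i.e. 158 fish in all
#'   (160 planned).
#' @param n_per_cell_ctm Count per design cell for the CTmax cohort
#'   (default 10, i.e. 160 fish).
#' @param mass_mean_by_cell List with elements `respirometry` and `ctm`,
#'   each a data frame `population` x `acclimation_temp` x `mass_g` of cell
#'   mean body masses. Defaults mirror the study's cohorts (respirometry
#'   fish around 110 g, lighter at 19 degrees C; CTmax fish around 50 g).
#' @param mass_cv Between-fish coefficient of variation of body mass within
#'   a cell (lognormal; default 0.12).
#' @param condition_k_by_cell Same structure as `mass_mean_by_cell` with
#'   column `k`: target Fulton condition factor per cell, used to derive
#'   fork length from mass.
#' @param length_cv Multiplicative noise CV on derived fork length.
#' @param ctm_mean_by_acclimation Named numeric, mean loss-of-equilibrium
#'   temperature (degrees C) per acclimation temperature.
#' @param ctm_sd Between-fish SD of the loss-of-equilibrium temperature.
#' @param rmr_ref,mmr_ref Named numeric whole-animal RMR / MMR anchors
#'   (mg O2 h^-1) at `reference_mass`, one per acclimation temperature.
#' @param rmr_mass_exponent,mmr_mass_exponent Allometric exponents b in
#'   rate ~ mass^b (defaults 1.12 and 0.82).
#' @param reference_mass Reference body mass in grams (default 108.6).
#' @param rmr_cv,mmr_cv Between-fish biological CV of the metabolic anchors.
#' @param mmr_pop_multiplier Named numeric multiplicative population effect
#'   on MMR (default: Lake Manitou 6% higher, others 1).
#' @param recovery_log_slope_by_acclimation Named numeric slope of the
#'   post-exhaustion recovery curve MO2(t) = MMR + b1 * ln(t), in
#'   mg O2 h^-1 per ln-minute; must be <= 0.
#' @param recovery_slope_pop_shift Named numeric additive population shift
#'   on the recovery slope (default: Lake Manitou steeper by -0.5).
#' @param recovery_cv Multiplicative noise CV per recovery window.
#' @param trace_noise_sd Gaussian noise SD on oxygen readings (mg l^-1).
#' @param background_slope Bacterial background oxygen decline in the
#'   chamber (mg l^-1 min^-1).
#' @param o2_start Dissolved oxygen at the start of a closed phase (mg l^-1).
#' @param sample_interval_s Probe sampling cadence in seconds.
#' @param chamber_volume Respirometer volume V in litres (default 1.1).
#' @param fish_density Tissue density (g ml^-1) used to convert mass to fish
#'   volume Vm = mass/1000/density litres.
#' @param n_rmr_slopes Number of closed-phase measurements averaged into the
#'   routine metabolic rate (default 3).
#' @param n_blank_traces Number of fishless background traces generated.
#' @param flush_min,measure_min Flush and measurement phase durations (min).
#' @param n_recovery_windows Number of post-chase measurement windows
#'   (default 8; with the default 5-min phases the schedule spans 75 min).
#' @param ramp_rate CTmax heating ramp in degrees C per minute (default 0.17).
#' @param chase_duration_mean_min,chase_duration_sd_min Chase-to-exhaustion
#'   duration distribution (minutes).
#' @param transfer_delay_min Delay between exhaustion and chamber re-entry.
#'
#' @return A validated list of class `"troutherm_config"`.
#' @export
generator_config <- function(
    populations = c("Myrt Lake", "Lake Louisa", "Opeongo Lake", "Lake Manitou"),
    acclimation_temps = c(8, 11, 15, 19),
    n_per_cell_respirometry = NULL,
    n_per_cell_ctm = 10,
    mass_mean_by_cell = NULL,
    mass_cv = 0.12,
    condition_k_by_cell = NULL,
    length_cv = 0.02,
    ctm_mean_by_acclimation = c(`8` = 26.1, `11` = 26.6, `15` = 28.1, `19` = 28.9),
    ctm_sd = 0.5,
    rmr_ref = c(`8` = 5.26, `11` = 8.2, `15` = 12.6, `19` = 13.4),
    mmr_ref = c(`8` = 33, `11` = 37, `15` = 41, `19` = 32),
    rmr_mass_exponent = 1.12,
    mmr_mass_exponent = 0.82,
    reference_mass = 108.6,
    rmr_cv = 0.10,
    mmr_cv = 0.10,
    mmr_pop_multiplier = NULL,
    recovery_log_slope_by_acclimation = c(`8` = -5.5, `11` = -6.0, `15` = -6.5, `19` = -4.0),
    recovery_slope_pop_shift = NULL,
    recovery_cv = 0.05,
    trace_noise_sd = 0.005,
    background_slope = 0.002,
    o2_start = 9.5,
    sample_interval_s = 5,
    chamber_volume = 1.1,
    fish_density = 1.0,
    n_rmr_slopes = 3,
    n_blank_traces = 8,
    flush_min = 5,
    measure_min = 5,
    n_recovery_windows = 8,
    ramp_rate = 0.17,
    chase_duration_mean_min = 4.75,
    chase_duration_sd_min = 0.5,
    transfer_delay_min = 0.2) {

  if (is.null(n_per_cell_respirometry)) {
    n_per_cell_respirometry <- default_cell_table(
      populations, acclimation_temps, "n",
      default_respirometry_n(populations, acclimation_temps))
  } else if (is.numeric(n_per_cell_respirometry) && length(n_per_cell_respirometry) == 1) {
    n_per_cell_respirometry <- default_cell_table(
      populations, acclimation_temps, "n", n_per_cell_respirometry)
  }
  if (is.numeric(n_per_cell_ctm) && length(n_per_cell_ctm) == 1) {
    n_per_cell_ctm <- default_cell_table(
      populations, acclimation_temps, "n", n_per_cell_ctm)
  }
  if (is.null(mass_mean_by_cell)) {
    mass_mean_by_cell <- list(
      respirometry = default_mass_table(populations, acclimation_temps, "respirometry"),
      ctm = default_mass_table(populations, acclimation_temps, "ctm"))
  }
  if (is.null(condition_k_by_cell)) {
    condition_k_by_cell <- list(
      respirometry = default_k_table(populations, acclimation_temps, "respirometry"),
      ctm = default_k_table(populations, acclimation_temps, "ctm"))
  }
  if (is.null(mmr_pop_multiplier)) {
    mmr_pop_multiplier <- stats::setNames(rep(1, length(populations)), populations)
    if ("Lake Manitou" %in% populations) mmr_pop_multiplier["Lake Manitou"] <- 1.06
  }
  if (is.null(recovery_slope_pop_shift)) {
    recovery_slope_pop_shift <- stats::setNames(rep(0, length(populations)), populations)
    if ("Lake Manitou" %in% populations) recovery_slope_pop_shift["Lake Manitou"] <- -0.5
  }

  config <- structure(list(
    populations = populations,
    acclimation_temps = acclimation_temps,
    n_per_cell_respirometry = n_per_cell_respirometry,
    n_per_cell_ctm = n_per_cell_ctm,
    mass_mean_by_cell = mass_mean_by_cell,
    mass_cv = mass_cv,
    condition_k_by_cell = condition_k_by_cell,
    length_cv = length_cv,
    ctm_mean_by_acclimation = ctm_mean_by_acclimation,
    ctm_sd = ctm_sd,
    rmr_ref = rmr_ref,
    mmr_ref = mmr_ref,
    rmr_mass_exponent = rmr_mass_exponent,
    mmr_mass_exponent = mmr_mass_exponent,
    reference_mass = reference_mass,
    rmr_cv = rmr_cv,
    mmr_cv = mmr_cv,
    mmr_pop_multiplier = mmr_pop_multiplier,
    recovery_log_slope_by_acclimation = recovery_log_slope_by_acclimation,
    recovery_slope_pop_shift = recovery_slope_pop_shift,
    recovery_cv = recovery_cv,
    trace_noise_sd = trace_noise_sd,
    background_slope = background_slope,
    o2_start = o2_start,
    sample_interval_s = sample_interval_s,
    chamber_volume = chamber_volume,
    fish_density = fish_density,
    n_rmr_slopes = n_rmr_slopes,
    n_blank_traces = n_blank_traces,
    flush_min = flush_min,
    measure_min = measure_min,
    n_recovery_windows = n_recovery_windows,
    ramp_rate = ramp_rate,
    chase_duration_mean_min = chase_duration_mean_min,
    chase_duration_sd_min = chase_duration_sd_min,
    transfer_delay_min = transfer_delay_min
  ), class = "troutherm_config")
  validate_config(config)
  config
}

#' Validate a generator configuration
#'
#' Checks counts, volumes, rates and the per-acclimation-temperature anchor
#' tables; raises a configuration error naming the offending field.
#'
#' @param config A `troutherm_config` object.
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "troutherm_config"))
    config_error("`config` must be a troutherm_config object")
  if (length(config$populations) < 1) config_error("populations: at least one label required")
  if (length(config$acclimation_temps) < 1) config_error("acclimation_temps: at least one temperature required")
  for (fld in c("n_per_cell_respirometry", "n_per_cell_ctm")) {
    tab <- config[[fld]]
    if (!is.data.frame(tab) || !all(c("population", "acclimation_temp", "n") %in% names(tab)))
      config_error(sprintf("%s: must be a data frame with population, acclimation_temp, n", fld))
    if (any(tab$n < 1)) config_error(sprintf("%s: all per-cell counts must be >= 1", fld))
  }
  if (config$chamber_volume <= 0) config_error("chamber_volume: must be > 0")
  if (config$fish_density <= 0) config_error("fish_density: must be > 0")
  if (config$ramp_rate <= 0) config_error("ramp_rate: must be > 0")
  if (config$mass_cv < 0) config_error("mass_cv: must be >= 0")
  if (any(config$recovery_log_slope_by_acclimation > 0))
    config_error("recovery_log_slope_by_acclimation: slopes must be <= 0")
  temps <- as.character(config$acclimation_temps)
  for (fld in c("ctm_mean_by_acclimation", "rmr_ref", "mmr_ref",
                "recovery_log_slope_by_acclimation")) {
    if (!all(temps %in% names(config[[fld]])))
      config_error(sprintf("%s: needs a named value for every acclimation temperature", fld))
  }
  if (!all(config$mmr_ref[temps] > config$rmr_ref[temps]))
    config_error("mmr_ref: must exceed rmr_ref at every acclimation temperature")
  if (config$n_recovery_windows < 1) config_error("n_recovery_windows: must be >= 1")
  if (config$measure_min <= 0 || config$flush_min < 0)
    config_error("measure_min/flush_min: measurement phase must be positive")
  invisible(config)
}

# --- built-in design tables (study cohorts) --------------------------------

default_respirometry_n <- function(populations, temps) {
  n <- matrix(10, nrow = length(populations), ncol = length(temps),
              dimnames = list(populations, as.character(temps)))
  # Myrt Lake cells at 8 and 11 degrees C ran one fish short
  if ("Myrt Lake" %in% populations) {
    for (tt in intersect(c("8", "11"), colnames(n))) n["Myrt Lake", tt] <- 9
  }
  n
}

default_cell_table <- function(populations, temps, col, values) {
  tab <- expand.grid(population = populations, acclimation_temp = temps,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (is.matrix(values)) {
    tab[[col]] <- values[cbind(tab$population, as.character(tab$acclimation_temp))]
  } else {
    tab[[col]] <- values
  }
  tab
}

# Cell mean body masses (g); respirometry cohort ~110 g with lighter fish at
# 19 degrees C, CTmax cohort ~50 g (the thermal trials ran on younger fish).
default_mass_table <- function(populations, temps, side) {
  full_pops <- c("Myrt Lake", "Lake Louisa", "Opeongo Lake", "Lake Manitou")
  resp <- matrix(c(
    116.9, 114.4, 111.4, 112.3,
    111.7, 116.5, 115.9, 120.7,
    116.5, 120.8, 111.7, 115.2,
     88.8,  84.3,  98.5,  84.1), nrow = 4, byrow = TRUE,
    dimnames = list(c("8", "11", "15", "19"), full_pops))
  ctm <- matrix(c(
    58.6, 52.0, 54.0, 51.7,
    53.0, 52.9, 59.9, 53.3,
    52.2, 33.7, 48.0, 46.2,
    47.0, 44.1, 51.5, 43.2), nrow = 4, byrow = TRUE,
    dimnames = list(c("8", "11", "15", "19"), full_pops))
  m <- if (side == "respirometry") resp else ctm
  fallback <- mean(m)
  vals <- matrix(fallback, nrow = length(populations), ncol = length(temps),
                 dimnames = list(populations, as.character(temps)))
  for (p in intersect(populations, colnames(m)))
    for (tt in intersect(as.character(temps), rownames(m)))
      vals[p, tt] <- m[tt, p]
  out <- default_cell_table(populations, temps, "mass_g", vals)
  out
}

# Target Fulton condition factor K per cell (respirometry fish plumper,
# especially at 19 degrees C).
default_k_table <- function(populations, temps, side) {
  full_pops <- c("Myrt Lake", "Lake Louisa", "Opeongo Lake", "Lake Manitou")
  resp <- matrix(c(
    1.3, 1.2, 1.2, 1.1,
    1.2, 1.2, 1.2, 1.1,
    1.4, 1.2, 1.3, 1.2,
    1.4, 1.3, 1.4, 1.2), nrow = 4, byrow = TRUE,
    dimnames = list(c("8", "11", "15", "19"), full_pops))
  ctm <- matrix(c(
    1.1, 1.1, 1.1, 1.0,
    1.2, 1.2, 1.1, 1.1,
    1.2, 1.1, 1.2, 1.0,
    1.2, 1.1, 1.2, 1.1), nrow = 4, byrow = TRUE,
    dimnames = list(c("8", "11", "15", "19"), full_pops))
  m <- if (side == "respirometry") resp else ctm
  vals <- matrix(mean(m), nrow = length(populations), ncol = length(temps),
                 dimnames = list(populations, as.character(temps)))
  for (p in intersect(populations, colnames(m)))
    for (tt in intersect(as.character(temps), rownames(m)))
      vals[p, tt] <- m[tt, p]
  default_cell_table(populations, temps, "k", vals)
}

#' Read a generator configuration from a YAML file
#'
#' Scalar fields override the defaults of [generator_config()]; named lists
#' become named numeric vectors (e.g. `rmr_ref: {8: 5.26, 11: 8.2, ...}`).
#'
#' @param path Path to a YAML file.
#' @return A `troutherm_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) io_error(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    config_error(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  raw <- lapply(raw, function(x) {
    if (is.list(x) && !is.null(names(x)) && all(vapply(x, is.numeric, TRUE)))
      unlist(x) else x
  })
  do.call(generator_config, raw)
}
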