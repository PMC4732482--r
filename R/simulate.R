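#' Simulate one closed-phase oxygen trace
#'
#' Produces a dissolved-oxygen time series for a fish respiring at a known
#' rate inside a closed respirometer: O2(t) = C0 - (MO2/((V - Vm) * 60) +
#' background) * t + Gaussian noise, sampled at the configured cadence over
#' the measurement phase. `fish = NULL` (or `true_mo2 = 0` with a fish)
#' yields the background-only behaviour used for blank chamber runs.
#'
#' @param true_mo2 True oxygen consumption in mg O2 h^-1 (>= 0).
#' @param fish One-row fish record (for mass -> volume) or NULL for a blank.
#' @param config A [generator_config()].
#' @param seed Integer seed (NULL consumes the current stream).
#' @param window_id Identifier for the measurement window.
#' @return An object of class `"o2_trace"`: list with `fish_id`,
#'   `window_id`, `samples` (data frame `time_min`, `o2_mg_per_l`),
#'   `chamber_volume`, `fish_volume`.
#' @export
simulate_closed_trace <- function(true_mo2, fish = NULL, config = generator_config(),
                                  seed = NULL, window_id = "w1") {
  if (true_mo2 < 0) param_error("true_mo2 must be >= 0")
  V <- config$chamber_volume
  Vm <- if (is.null(fish)) 0 else fish$mass_g / 1000 / config$fish_density
  if (Vm >= V) geometry_error(sprintf(
    "fish volume (%.3f l) must be smaller than chamber volume (%.3f l)", Vm, V))
  times <- seq(0, config$measure_min, by = config$sample_interval_s / 60)
  rate <- true_mo2 / ((V - Vm) * 60) + config$background_slope
  with_seed(seed, {
    o2 <- config$o2_start - rate * times +
      stats::rnorm(length(times), 0, config$trace_noise_sd)
    structure(list(
      fish_id = if (is.null(fish)) "blank" else fish$fish_id,
      window_id = window_id,
      samples = data.frame(time_min = times, o2_mg_per_l = o2),
      chamber_volume = V,
      fish_volume = Vm), class = "o2_trace")
  })
}

#' Simulate a post-exhaustion recovery series
#'
#' Models oxygen consumption after a chase to exhaustion as
#' MO2(t) = MMR + b1 * ln(t), with t the measurement-window midpoint in
#' minutes since chamber re-entry and b1 <= 0 the recovery slope for the
#' fish's design cell. The default schedule is eight 5-min windows
#' separated by 5-min flushes (midpoints 2.5, 12.5, ..., 72.5 min; the last
#' window ends at minute 75). Values are floored at `rmr_floor` so late
#' recovery does not undershoot rest, and multiplied by lognormal window
#' noise with CV `recovery_cv`.
#'
#' @param fish One-row fish record.
#' @param mmr_true True maximal metabolic rate (mg O2 h^-1, > 0).
#' @param config A [generator_config()].
#' @param seed Integer seed (NULL consumes the current stream).
#' @param beta1 Recovery slope (mg O2 h^-1 per ln-minute); defaults to the
#'   configured value for the fish's cell.
#' @param rmr_floor Floor applied to the series (default 0 = no floor).
#' @return An object of class `"recovery_series"`: list with `fish_id`,
#'   `measurements` (data frame `window_index`, `midpoint_min`,
#'   `mo2_mg_per_h`), `chase_duration_min`, `transfer_delay_min`.
#' @export
simulate_recovery_series <- function(fish, mmr_true, config = generator_config(),
                                     seed = NULL, beta1 = NULL, rmr_floor = 0) {
  if (mmr_true <= 0) param_error("mmr_true must be > 0")
  if (is.null(beta1)) {
    beta1 <- config$recovery_log_slope_by_acclimation[as.character(fish$acclimation_temp)] +
      config$recovery_slope_pop_shift[[fish$population]]
  }
  if (beta1 > 0) param_error("recovery slope beta1 must be <= 0")
  k <- config$n_recovery_windows
  midpoints <- (seq_len(k) - 1) * (config$measure_min + config$flush_min) +
    config$measure_min / 2
  with_seed(seed, {
    truth <- pmax(mmr_true + beta1 * log(midpoints), rmr_floor)
    if (config$recovery_cv > 0) {
      p <- lnorm_pars(1, config$recovery_cv)
      obs <- truth * stats::rlnorm(k, p$meanlog, p$sdlog)
    } else obs <- truth
    obs <- pmax(obs, rmr_floor)
    chase <- max(stats::rnorm(1, config$chase_duration_mean_min,
                              config$chase_duration_sd_min),
                 config$chase_duration_mean_min / 2)
    structure(list(
      fish_id = fish$fish_id,
      measurements = data.frame(window_index = seq_len(k),
                                midpoint_min = midpoints,
                                mo2_mg_per_h = obs),
      chase_duration_min = chase,
      transfer_delay_min = config$transfer_delay_min), class = "recovery_series")
  })
}

#' Simulate critical thermal maximum trials for a cohort
#'
#' Each fish's loss-of-equilibrium (LOE) temperature is drawn
#' Normal(ctm_mean(acclimation temp), ctm_sd) and converted to an event
#' time on a linear ramp starting at the acclimation temperature and
#' heating at the configured rate. Fish sharing an acclimation temperature
#' are split across two challenge trials, mirroring the protocol of running
#' mixed-population groups together.
#'
#' @param cohort Data frame from [build_cohort()].
#' @param config A [generator_config()].
#' @param seed Integer seed (NULL consumes the current stream).
#' @param max_retries Resampling attempts when a draw falls at or below the
#'   ramp start (then an error is raised).
#' @return A list of `"ctm_trial"` objects: each has `trial_id`, `ramp`
#'   (a [ramp_schedule()]) and `events` (data frame `fish_id`,
#'   `loe_time_min`, `loe_temp_C`).
#' @export
simulate_ctm_cohort <- function(cohort, config = generator_config(), seed = NULL,
                                max_retries = 100) {
  if (nrow(cohort) == 0) data_error("cohort must be nonempty")
  validate_config(config)
  with_seed(seed, {
    trials <- list()
    for (temp in sort(unique(cohort$acclimation_temp))) {
      sub <- cohort[cohort$acclimation_temp == temp, , drop = FALSE]
      mean_ctm <- config$ctm_mean_by_acclimation[[as.character(temp)]]
      # split each population's fish evenly across the two challenge tanks
      grp <- integer(nrow(sub))
      for (p in unique(sub$population)) {
        ix <- which(sub$population == p)
        grp[ix] <- rep_len(1:2, length(ix))
      }
      ramp <- ramp_schedule(start_temp = temp, rate = config$ramp_rate)
      loe_temp <- vapply(seq_len(nrow(sub)), function(i) {
        for (try in seq_len(max_retries)) {
          x <- stats::rnorm(1, mean_ctm, config$ctm_sd)
          if (x > temp) return(x)
        }
        param_error(sprintf(
          "could not draw a loss-of-equilibrium temperature above the ramp start (%g C)", temp))
      }, numeric(1))
      loe_time <- (loe_temp - temp) / config$ramp_rate
      for (g in 1:2) {
        ix <- which(grp == g)
        if (!length(ix)) next
        trials[[length(trials) + 1]] <- structure(list(
          trial_id = sprintf("ctm_%g_%d", temp, g),
          ramp = ramp,
          events = data.frame(fish_id = sub$fish_id[ix],
                              loe_time_min = loe_time[ix],
                              loe_temp_C = loe_temp[ix],
                              stringsAsFactors = FALSE)),
          class = "ctm_trial")
      }
    }
    trials
  })
}
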