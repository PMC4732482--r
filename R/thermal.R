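#' Linear heating ramp for a thermal challenge trial
#'
#' @param start_temp Starting water temperature in degrees C.
#' @param rate Heating rate in degrees C per minute (> 0).
#' @return An object of class `"ramp_schedule"`.
#' @export
ramp_schedule <- function(start_temp, rate = 0.17) {
  if (rate <= 0) domain_error("ramp rate must be > 0")
  structure(list(start_temp = start_temp, rate = rate), class = "ramp_schedule")
}

#' Water temperature at a given time on a ramp
#'
#' @param ramp A [ramp_schedule()].
#' @param t Time in minutes since ramp start (>= 0; vectorised).
#' @return Temperature in degrees C: `start_temp + rate * t`.
#' @export
temperature_at <- function(ramp, t) {
  if (any(t < 0)) domain_error("time on the ramp must be >= 0")
  ramp$start_temp + ramp$rate * t
}

#' Time at which a ramp reaches a given temperature
#'
#' Inverse of [temperature_at()].
#'
#' @param ramp A [ramp_schedule()].
#' @param temp Temperature in degrees C (>= start temperature; vectorised).
#' @return Time in minutes since ramp start.
#' @export
time_at_temperature <- function(ramp, temp) {
  if (any(temp < ramp$start_temp)) domain_error("temperature below ramp start")
  (temp - ramp$start_temp) / ramp$rate
}

#' Critical thermal maxima for one ramping trial
#'
#' Converts each loss-of-equilibrium event into a CTmax value: events
#' recorded as times are mapped through the ramp; events recorded directly
#' as temperatures pass through unchanged. Times take precedence when both
#' are present (they agree by construction for simulated trials).
#'
#' @param trial A `"ctm_trial"`: list with `trial_id`, `ramp` and `events`
#'   (data frame with `fish_id` and `loe_time_min` and/or `loe_temp_C`).
#' @return Data frame `fish_id`, `ctm_C`, joinable to the fish metadata.
#' @export
ctm_values <- function(trial) {
  ev <- trial$events
  if (is.null(ev) || nrow(ev) == 0) data_error("trial has no events")
  if (anyDuplicated(ev$fish_id)) data_error("more than one event for a fish")
  times <- if ("loe_time_min" %in% names(ev)) ev$loe_time_min else rep(NA_real_, nrow(ev))
  temps <- if ("loe_temp_C" %in% names(ev)) ev$loe_temp_C else rep(NA_real_, nrow(ev))
  if (any(is.na(times) & is.na(temps))) data_error(
    "every event needs a loss-of-equilibrium time or temperature")
  ctm <- temps
  use_time <- !is.na(times)
  if (any(use_time)) ctm[use_time] <- temperature_at(trial$ramp, times[use_time])
  data.frame(fish_id = ev$fish_id, ctm_C = ctm, stringsAsFactors = FALSE)
}

#' Critical thermal maxima for a list of trials
#'
#' @param trials List of `"ctm_trial"` objects.
#' @return Row-bound data frame of [ctm_values()] results with a
#'   `trial_id` column.
#' @export
ctm_values_all <- function(trials) {
  out <- lapply(trials, function(tr) cbind(trial_id = tr$trial_id, ctm_values(tr)))
  do.call(rbind, out)
}
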