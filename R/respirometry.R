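#' Fit the oxygen-decline slope of a closed-phase trace
#'
#' Ordinary least-squares regression of dissolved oxygen on time over the
#' retained samples. The decline rate is the negated fitted slope; a rising
#' trace (negative decline) is reported as-is with a QC flag rather than
#' clamped, unless `clamp_negative = TRUE`.
#'
#' @param trace An `"o2_trace"` object or a data frame with columns
#'   `time_min` and `o2_mg_per_l`.
#' @param trim_start Minutes discarded from the start of the trace
#'   (default 0).
#' @param clamp_negative Clamp negative declines at zero (default FALSE).
#' @return An object of class `"slope_fit"`: `decline_rate` (mg l^-1
#'   min^-1), `intercept`, `r_squared`, `n_points`, `negative_decline`.
#' @export
fit_o2_slope <- function(trace, trim_start = 0, clamp_negative = FALSE) {
  samples <- if (inherits(trace, "o2_trace")) trace$samples else trace
  keep <- samples$time_min >= trim_start
  samples <- samples[keep, , drop = FALSE]
  if (nrow(samples) < 3) data_error("fewer than 3 samples remain after trimming")
  if (stats::var(samples$time_min) == 0) data_error("zero variance in sample times")
  fit <- stats::lm(o2_mg_per_l ~ time_min, data = samples)
  slope <- unname(stats::coef(fit)[["time_min"]])
  decline <- -slope
  negative <- decline < 0
  if (negative && clamp_negative) decline <- 0
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((samples$o2_mg_per_l - mean(samples$o2_mg_per_l))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(
    decline_rate = decline,
    intercept = unname(stats::coef(fit)[[1]]),
    r_squared = r2,
    n_points = nrow(samples),
    negative_decline = negative,
    fish_id = if (inherits(trace, "o2_trace")) trace$fish_id else NA_character_),
    class = "slope_fit")
}

#' Oxygen consumption from a fitted decline rate
#'
#' Applies the whole-animal conversion MO2 (mg O2 h^-1) =
#' (decline rate - blank rate) * (V - Vm) * 60, where V is the respirometer
#' volume and Vm the fish volume (litres). The bacterial background rate is
#' subtracted on the concentration-rate scale before the volume
#' multiplication.
#'
#' @param fit A `"slope_fit"` or a numeric decline rate (mg l^-1 min^-1).
#' @param V Chamber volume in litres.
#' @param Vm Fish volume in litres (mass in g / 1000 for unit density).
#' @param blank_rate Background decline rate (mg l^-1 min^-1, >= 0).
#' @return Oxygen consumption in mg O2 h^-1.
#' @export
mo2_from_slope <- function(fit, V, Vm = 0, blank_rate = 0) {
  decline <- if (inherits(fit, "slope_fit")) fit$decline_rate else fit
  if (V <= Vm) geometry_error(sprintf(
    "chamber volume (%g l) must exceed fish volume (%g l)", V, Vm))
  if (blank_rate < 0) param_error("blank_rate must be >= 0")
  (decline - blank_rate) * (V - Vm) * 60
}

#' Routine metabolic rate from repeated closed-phase measurements
#'
#' Arithmetic mean of the per-window oxygen consumption values; the
#' protocol expects three measurement windows, so a different count is
#' flagged (attribute `count_flag`) but not an error.
#'
#' @param mo2_values Numeric vector of MO2 values (mg O2 h^-1).
#' @param expected_n Expected number of measurements (default 3).
#' @return The mean MO2 with attribute `count_flag`.
#' @export
routine_mr <- function(mo2_values, expected_n = 3) {
  if (length(mo2_values) == 0) data_error("no MO2 values supplied")
  out <- mean(mo2_values)
  attr(out, "count_flag") <- length(mo2_values) != expected_n
  out
}

#' Fit the logarithmic post-exhaustion recovery curve
#'
#' OLS regression of MO2 on the natural log of the window midpoint time
#' since chamber re-entry: MO2(t) = b0 + b1 ln(t). The maximal metabolic
#' rate is the fitted value at `eval_time` minutes; at the default
#' `eval_time = 1` (where ln t = 0) this is exactly the curve's intercept,
#' the conventional back-extrapolated estimate of the rate immediately
#' after exhaustion. `beta1` is the recovery-rate statistic (decline in
#' metabolic rate per ln-minute; more negative = faster recovery).
#'
#' @param series A `"recovery_series"` or a data frame with columns
#'   `midpoint_min` and `mo2_mg_per_h`.
#' @param eval_time Time (min, > 0) at which the curve is evaluated for the
#'   MMR estimate; e.g. 0.25 to extrapolate to the ~15 s transfer time.
#' @return An object of class `"recovery_fit"`: `beta0`, `beta1`,
#'   `mmr_estimate`, `eval_time`, `r_squared`, `n`, `fish_id`.
#' @export
fit_recovery_curve <- function(series, eval_time = 1) {
  meas <- if (inherits(series, "recovery_series")) series$measurements else series
  if (nrow(meas) < 3) data_error("at least 3 recovery measurements required")
  if (any(meas$midpoint_min <= 0)) data_error("window midpoints must be > 0 (log undefined)")
  if (eval_time <= 0) domain_error("eval_time must be > 0")
  d <- data.frame(lnt = log(meas$midpoint_min), mo2 = meas$mo2_mg_per_h)
  fit <- stats::lm(mo2 ~ lnt, data = d)
  b0 <- unname(stats::coef(fit)[[1]])
  b1 <- unname(stats::coef(fit)[["lnt"]])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((d$mo2 - mean(d$mo2))^2)
  structure(list(
    beta0 = b0,
    beta1 = b1,
    mmr_estimate = b0 + b1 * log(eval_time),
    eval_time = eval_time,
    r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
    n = nrow(meas),
    fish_id = if (inherits(series, "recovery_series")) series$fish_id else NA_character_),
    class = "recovery_fit")
}

#' Highest observed post-chase oxygen consumption
#'
#' The maximum measured recovery value, an alternative (non-extrapolated)
#' MMR estimate; ties are broken in favour of the earliest window.
#'
#' @param series A `"recovery_series"` or data frame as in
#'   [fit_recovery_curve()].
#' @return List with `value` (mg O2 h^-1), `window_index`, `fish_id`.
#' @export
mmr_peak <- function(series) {
  meas <- if (inherits(series, "recovery_series")) series$measurements else series
  if (nrow(meas) == 0) data_error("empty recovery series")
  i <- which.max(meas$mo2_mg_per_h) # which.max returns the first maximum
  list(value = meas$mo2_mg_per_h[i],
       window_index = if ("window_index" %in% names(meas)) meas$window_index[i] else i,
       fish_id = if (inherits(series, "recovery_series")) series$fish_id else NA_character_)
}

#' Combine per-fish estimates into a metabolic summary
#'
#' Metabolic scope is the difference MMR - RMR; a non-positive scope is
#' permitted but flagged. Inputs carrying fish identifiers must agree.
#'
#' @param rmr Routine metabolic rate (from [routine_mr()]).
#' @param recovery_fit A `"recovery_fit"` (supplies MMR and recovery slope).
#' @param peak Result of [mmr_peak()].
#' @param fish_id Fish identifier; defaults to the one carried by
#'   `recovery_fit`.
#' @return One-row data frame: `fish_id`, `rmr`, `mmr`, `mmr_peak`,
#'   `scope`, `recovery_slope`, `qc_flags`.
#' @export
summarize_fish <- function(rmr, recovery_fit, peak, fish_id = NULL) {
  ids <- c(recovery_fit$fish_id, peak$fish_id, fish_id)
  ids <- unique(ids[!is.na(ids)])
  if (length(ids) > 1) data_error(sprintf(
    "inputs belong to different fish: %s", paste(ids, collapse = ", ")))
  mmr <- recovery_fit$mmr_estimate
  scope <- mmr - as.numeric(rmr)
  flags <- character(0)
  if (isTRUE(attr(rmr, "count_flag"))) flags <- c(flags, "rmr_count")
  if (scope <= 0) flags <- c(flags, "nonpositive_scope")
  data.frame(
    fish_id = if (length(ids)) ids else NA_character_,
    rmr = as.numeric(rmr),
    mmr = mmr,
    mmr_peak = peak$value,
    scope = scope,
    recovery_slope = recovery_fit$beta1,
    qc_flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE)
}
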