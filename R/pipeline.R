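#' Simulate a complete acclimation experiment
#'
#' Generates both cohorts (respirometry and CTmax), per-fish latent
#' metabolic rates, three closed-phase oxygen traces per respirometry fish,
#' background (blank) chamber traces, the eight-window post-exhaustion
#' recovery series, and the CTmax ramping trials. All randomness is driven
#' by the single `seed`, so repeated calls are bit-identical.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return List with `fish` (respirometry cohort with truth columns),
#'   `traces` (long data frame of all closed-phase samples, blanks
#'   included), `recovery` (long data frame of recovery measurements),
#'   `ctm_cohort`, `ctm_trials`, and `config`.
#' @export
simulate_experiment <- function(config = generator_config(), seed = 1) {
  validate_config(config)
  with_seed(seed, {
    fish <- build_cohort(config, seed = NULL, design = "respirometry")
    fish <- true_metabolic_rates(fish, config, seed = NULL)
    ctm_cohort <- build_cohort(config, seed = NULL, design = "ctm")

    trace_list <- list()
    for (i in seq_len(nrow(fish))) {
      f <- fish[i, ]
      for (w in seq_len(config$n_rmr_slopes)) {
        tr <- simulate_closed_trace(f$rmr_true, f, config, seed = NULL,
                                    window_id = sprintf("rmr%d", w))
        trace_list[[length(trace_list) + 1]] <- data.frame(
          fish_id = tr$fish_id, window_id = tr$window_id,
          time_min = tr$samples$time_min, o2_mg_per_l = tr$samples$o2_mg_per_l,
          temp_C = f$acclimation_temp, stringsAsFactors = FALSE)
      }
    }
    for (b in seq_len(config$n_blank_traces)) {
      tr <- simulate_closed_trace(0, NULL, config, seed = NULL,
                                  window_id = sprintf("blank%d", b))
      trace_list[[length(trace_list) + 1]] <- data.frame(
        fish_id = "blank", window_id = tr$window_id,
        time_min = tr$samples$time_min, o2_mg_per_l = tr$samples$o2_mg_per_l,
        temp_C = NA_real_, stringsAsFactors = FALSE)
    }
    traces <- do.call(rbind, trace_list)

    recovery_list <- lapply(seq_len(nrow(fish)), function(i) {
      f <- fish[i, ]
      rs <- simulate_recovery_series(f, f$mmr_true, config, seed = NULL,
                                     beta1 = f$recovery_slope_true,
                                     rmr_floor = f$rmr_true)
      cbind(fish_id = f$fish_id, rs$measurements,
            chase_duration_min = rs$chase_duration_min)
    })
    recovery <- do.call(rbind, recovery_list)

    ctm_trials <- simulate_ctm_cohort(ctm_cohort, config, seed = NULL)

    list(fish = fish, traces = traces, recovery = recovery,
         ctm_cohort = ctm_cohort, ctm_trials = ctm_trials, config = config)
  })
}

#' Estimate the background (blank) chamber respiration rate
#'
#' Mean fitted oxygen-decline rate over all fishless traces.
#'
#' @param traces Long trace data frame (as in [simulate_experiment()]).
#' @param blank_id Sentinel fish id marking blank runs (default "blank").
#' @return Background decline rate in mg l^-1 min^-1 (0 if no blanks).
#' @export
estimate_blank_rate <- function(traces, blank_id = "blank") {
  bl <- traces[traces$fish_id == blank_id, , drop = FALSE]
  if (nrow(bl) == 0) return(0)
  rates <- vapply(split(bl, bl$window_id),
                  function(w) fit_o2_slope(w)$decline_rate, numeric(1))
  mean(rates)
}

#' Reduce traces and recovery series to per-fish metabolic summaries
#'
#' For each fish: fits the oxygen-decline slope of every closed-phase
#' window, converts slopes to MO2 with background subtraction, averages
#' the routine windows into RMR, fits the logarithmic recovery curve for
#' the back-extrapolated MMR and recovery slope, and records the highest
#' observed post-chase value. Scope is MMR minus RMR.
#'
#' @param traces Long trace data frame (`fish_id`, `window_id`, `time_min`,
#'   `o2_mg_per_l`).
#' @param recovery Long recovery data frame (`fish_id`, `window_index`,
#'   `midpoint_min`, `mo2_mg_per_h`).
#' @param fish Fish metadata (`fish_id`, `mass_g`, ...).
#' @param chamber_volume Respirometer volume V in litres.
#' @param fish_density Tissue density (g ml^-1) for mass -> volume.
#' @param blank_rate Background decline rate (mg l^-1 min^-1); default is
#'   estimated from the blank traces.
#' @param eval_time Evaluation time (min) for the back-extrapolated MMR.
#' @param trim_start Minutes trimmed from each trace before slope fitting.
#' @return Data frame: `fish_id`, `rmr`, `mmr`, `mmr_peak`, `scope`,
#'   `recovery_slope`, `qc_flags`.
#' @export
process_respirometry <- function(traces, recovery, fish, chamber_volume = 1.1,
                                 fish_density = 1.0,
                                 blank_rate = estimate_blank_rate(traces),
                                 eval_time = 1, trim_start = 0) {
  need <- setdiff(c("fish_id", "window_id", "time_min", "o2_mg_per_l"), names(traces))
  if (length(need)) io_error(sprintf("traces: missing column(s) %s", paste(need, collapse = ", ")))
  need <- setdiff(c("fish_id", "midpoint_min", "mo2_mg_per_h"), names(recovery))
  if (length(need)) io_error(sprintf("recovery: missing column(s) %s", paste(need, collapse = ", ")))
  out <- lapply(fish$fish_id, function(id) {
    ftr <- traces[traces$fish_id == id, , drop = FALSE]
    frec <- recovery[recovery$fish_id == id, , drop = FALSE]
    if (nrow(ftr) == 0 || nrow(frec) == 0)
      data_error(sprintf("fish %s has no traces or no recovery series", id))
    Vm <- fish$mass_g[fish$fish_id == id] / 1000 / fish_density
    slopes <- lapply(split(ftr, ftr$window_id), fit_o2_slope, trim_start = trim_start)
    mo2 <- vapply(slopes, mo2_from_slope, numeric(1),
                  V = chamber_volume, Vm = Vm, blank_rate = blank_rate)
    rmr <- routine_mr(mo2)
    frec <- frec[order(frec$midpoint_min), , drop = FALSE]
    rfit <- fit_recovery_curve(frec, eval_time = eval_time)
    peak <- mmr_peak(frec)
    sm <- summarize_fish(rmr, rfit, peak, fish_id = id)
    if (any(vapply(slopes, function(s) s$negative_decline, logical(1))))
      sm$qc_flags <- paste(c(strsplit(sm$qc_flags, ";")[[1]], "negative_decline"),
                           collapse = ";")
    sm
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble the per-fish analysis dataset
#'
#' Joins fish metadata with metabolic summaries and adds Fulton's condition
#' factor.
#'
#' @param fish Fish metadata data frame.
#' @param summaries Output of [process_respirometry()].
#' @return Data frame keyed by `fish_id`.
#' @export
build_analysis_dataset <- function(fish, summaries) {
  if (anyDuplicated(fish$fish_id)) data_error("duplicate fish_id in metadata")
  d <- merge(fish, summaries, by = "fish_id", sort = FALSE)
  d$condition_factor <- condition_factor(d$mass_g, d$fork_length_cm)
  d
}

# Response -> analysis recipe used by run_pipeline(): whether a mass
# covariate enters (ANCOVA) and which scales are log10.
response_plan <- function() {
  list(
    ctm = list(kind = "anova", log10 = FALSE),
    rmr = list(kind = "ancova", log10 = TRUE, log10_cov = TRUE),
    mmr = list(kind = "ancova", log10 = TRUE, log10_cov = TRUE),
    scope = list(kind = "ancova", log10 = TRUE, log10_cov = TRUE),
    recovery_slope = list(kind = "ancova", log10 = FALSE, log10_cov = FALSE),
    mass_g = list(kind = "anova", log10 = TRUE),
    fork_length_cm = list(kind = "anova", log10 = FALSE),
    condition_factor = list(kind = "anova", log10 = TRUE))
}

analyze_response <- function(data, response, plan, reference_mass, alpha, ss_type) {
  fit <- if (plan$kind == "ancova") {
    two_way_ancova(data, response, log10_response = plan$log10,
                   log10_covariate = plan$log10_cov, ss_type = ss_type)
  } else {
    two_way_anova(data, response, log10_response = plan$log10, ss_type = ss_type)
  }
  res <- list(response = response, kind = plan$kind, fit = fit,
              adjusted_means = suppressMessages(
                adjusted_means(fit, "acclimation_temp", reference_mass)))
  ptab <- fit$table
  for (fct in c("population", "acclimation_temp")) {
    p <- ptab$p[ptab$term == fct]
    if (length(p) == 1 && !is.na(p) && p < alpha)
      res[[paste0("tukey_", fct)]] <- suppressMessages(tukey_hsd(fit, fct, alpha))
  }
  res
}

#' Run the full simulation-to-inference pipeline
#'
#' Simulates an experiment (or consumes a pre-simulated one), reduces the
#' respirometry and CTmax raw data to per-fish values, and analyses the
#' eight responses: CTmax, RMR, MMR, metabolic scope, recovery slope, body
#' mass, fork length and condition factor. Metabolic responses are
#' analysed by mass-covariate ANCOVA with adjusted means at
#' `reference_mass`; CTmax and body-size responses by two-factor ANOVA.
#' Tukey HSD tables are produced for each factor with a significant
#' omnibus F. When `out_dir` is given, all tables are written as CSV with
#' a seed/config-hash header plus a JSON manifest and a plain-text report;
#' outputs are byte-identical for a fixed seed.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed for the simulation.
#' @param out_dir Optional output directory.
#' @param reference_mass Reference body mass (g) for adjusted means.
#' @param alpha Significance level gating the Tukey follow-ups.
#' @param eval_time Back-extrapolation time (min) for MMR.
#' @param ss_type Sum-of-squares type, `"I"` or `"III"`.
#' @param sim Optional pre-built result of [simulate_experiment()].
#' @return List of class `"troutherm_run"`: `design` (cell counts),
#'   `resp_data`, `ctm_data`, `analyses` (one element per response),
#'   `blank_rate`, `manifest`.
#' @export
run_pipeline <- function(config = generator_config(), seed = 1, out_dir = NULL,
                         reference_mass = 108.6, alpha = 0.05, eval_time = 1,
                         ss_type = "I", sim = NULL) {
  if (is.null(sim)) sim <- simulate_experiment(config, seed)
  blank_rate <- estimate_blank_rate(sim$traces)
  summaries <- process_respirometry(
    sim$traces, sim$recovery, sim$fish,
    chamber_volume = config$chamber_volume, fish_density = config$fish_density,
    blank_rate = blank_rate, eval_time = eval_time)
  resp_data <- build_analysis_dataset(sim$fish, summaries)
  ctm_tab <- ctm_values_all(sim$ctm_trials)
  ctm_data <- merge(sim$ctm_cohort, ctm_tab, by = "fish_id", sort = FALSE)
  names(ctm_data)[names(ctm_data) == "ctm_C"] <- "ctm"

  plans <- response_plan()
  analyses <- list()
  for (resp in names(plans)) {
    dat <- if (resp == "ctm") ctm_data else resp_data
    analyses[[resp]] <- analyze_response(dat, resp, plans[[resp]],
                                         reference_mass, alpha, ss_type)
  }

  design <- as.data.frame(table(resp_data$population, resp_data$acclimation_temp),
                          stringsAsFactors = FALSE)
  names(design) <- c("population", "acclimation_temp", "n_respirometry")
  ctm_counts <- as.data.frame(table(ctm_data$population, ctm_data$acclimation_temp),
                              stringsAsFactors = FALSE)
  design$n_ctm <- ctm_counts$Freq[match(paste(design$population, design$acclimation_temp),
                                        paste(ctm_counts$Var1, ctm_counts$Var2))]

  manifest <- list(seed = seed, config_hash = config_hash(config),
                   package_version = as.character(utils::packageVersion("troutherm")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   n_respirometry = nrow(resp_data), n_ctm = nrow(ctm_data),
                   reference_mass = reference_mass, alpha = alpha,
                   eval_time = eval_time, ss_type = ss_type,
                   blank_rate = blank_rate)
  run <- structure(list(design = design, resp_data = resp_data, ctm_data = ctm_data,
                        analyses = analyses, blank_rate = blank_rate,
                        manifest = manifest, sim = sim),
                   class = "troutherm_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Deterministic hash of a generator configuration
#'
#' MD5 of the serialized configuration, recorded in every output header so
#' a run can be traced back to its exact parameter set.
#'
#' @param config A `troutherm_config`.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(config, NULL, version = 2), tf)
  unname(tools::md5sum(tf))
}
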