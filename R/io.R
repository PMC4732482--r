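# CSV interchange: one header line, UTF-8, '.' decimal separator; every
# file written by a run carries a '#' comment line with the seed and the
# config hash so outputs are traceable and reproducible.

write_stamped_csv <- function(df, path, seed = NULL, hash = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(seed))
    writeLines(sprintf("# seed=%s config_hash=%s", seed, hash %||% "NA"), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_schema_csv <- function(path, required) {
  if (!file.exists(path)) io_error(sprintf("input file not found: %s", path))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) io_error(sprintf(
    "%s: missing column(s) %s", path, paste(missing, collapse = ", ")))
  df
}

#' Write a simulated experiment to CSV files
#'
#' Emits the interchange schemas consumed by the processing steps:
#' `fish.csv`, `ctm_fish.csv` (metadata), `traces.csv`, `recovery.csv`,
#' `ctm_events.csv`.
#'
#' @param sim Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the file headers.
#' @return The directory, invisibly.
#' @export
write_simulated_data <- function(sim, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(sim$config)
  meta_cols <- c("fish_id", "population", "acclimation_temp", "mass_g",
                 "fork_length_cm", "tank")
  fish <- sim$fish[, meta_cols]
  names(fish)[names(fish) == "acclimation_temp"] <- "acclimation_temp_C"
  write_stamped_csv(fish, file.path(dir, "fish.csv"), seed, hash)
  ctm_fish <- sim$ctm_cohort[, meta_cols]
  names(ctm_fish)[names(ctm_fish) == "acclimation_temp"] <- "acclimation_temp_C"
  write_stamped_csv(ctm_fish, file.path(dir, "ctm_fish.csv"), seed, hash)
  write_stamped_csv(sim$traces, file.path(dir, "traces.csv"), seed, hash)
  write_stamped_csv(sim$recovery, file.path(dir, "recovery.csv"), seed, hash)
  events <- do.call(rbind, lapply(sim$ctm_trials, function(tr) data.frame(
    trial_id = tr$trial_id,
    fish_id = tr$events$fish_id,
    start_temp_C = tr$ramp$start_temp,
    ramp_rate_C_per_min = tr$ramp$rate,
    loe_time_min = tr$events$loe_time_min,
    stringsAsFactors = FALSE)))
  write_stamped_csv(events, file.path(dir, "ctm_events.csv"), seed, hash)
  invisible(dir)
}

#' Read a simulated experiment back from CSV files
#'
#' Validates the schemas written by [write_simulated_data()] and
#' reconstitutes the trial objects; an I/O error names the file and the
#' missing column.
#'
#' @param dir Directory written by [write_simulated_data()].
#' @return List with `fish`, `ctm_cohort`, `traces`, `recovery`,
#'   `ctm_trials`.
#' @export
read_simulated_data <- function(dir) {
  fish <- read_schema_csv(file.path(dir, "fish.csv"),
                          c("fish_id", "population", "acclimation_temp_C",
                            "mass_g", "fork_length_cm", "tank"))
  names(fish)[names(fish) == "acclimation_temp_C"] <- "acclimation_temp"
  ctm_fish <- read_schema_csv(file.path(dir, "ctm_fish.csv"),
                              c("fish_id", "population", "acclimation_temp_C",
                                "mass_g", "fork_length_cm", "tank"))
  names(ctm_fish)[names(ctm_fish) == "acclimation_temp_C"] <- "acclimation_temp"
  traces <- read_schema_csv(file.path(dir, "traces.csv"),
                            c("fish_id", "window_id", "time_min", "o2_mg_per_l"))
  recovery <- read_schema_csv(file.path(dir, "recovery.csv"),
                              c("fish_id", "window_index", "midpoint_min",
                                "mo2_mg_per_h"))
  events <- read_schema_csv(file.path(dir, "ctm_events.csv"),
                            c("trial_id", "fish_id", "start_temp_C",
                              "ramp_rate_C_per_min", "loe_time_min"))
  trials <- lapply(split(events, events$trial_id), function(ev) {
    structure(list(trial_id = ev$trial_id[1],
                   ramp = ramp_schedule(ev$start_temp_C[1], ev$ramp_rate_C_per_min[1]),
                   events = ev[, c("fish_id", "loe_time_min")]),
              class = "ctm_trial")
  })
  list(fish = fish, ctm_cohort = ctm_fish, traces = traces,
       recovery = recovery, ctm_trials = unname(trials))
}

#' Write all tables, the manifest and the text report for a run
#'
#' @param run A `"troutherm_run"` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- run$manifest$seed
  hash <- run$manifest$config_hash
  write_stamped_csv(run$design, file.path(dir, "design_summary.csv"), seed, hash)
  write_stamped_csv(run$resp_data, file.path(dir, "per_fish_summary.csv"), seed, hash)
  write_stamped_csv(run$ctm_data, file.path(dir, "ctm_per_fish.csv"), seed, hash)
  for (resp in names(run$analyses)) {
    a <- run$analyses[[resp]]
    write_stamped_csv(a$fit$table, file.path(dir, sprintf("anova_%s.csv", resp)),
                      seed, hash)
    write_stamped_csv(a$adjusted_means,
                      file.path(dir, sprintf("adjusted_means_%s.csv", resp)),
                      seed, hash)
    for (fct in c("population", "acclimation_temp")) {
      tk <- a[[paste0("tukey_", fct)]]
      if (!is.null(tk))
        write_stamped_csv(as.data.frame(tk),
                          file.path(dir, sprintf("tukey_%s_%s.csv", resp, fct)),
                          seed, hash)
    }
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(render_report(run), file.path(dir, "report.txt"))
  invisible(dir)
}

#' Plain-text narrative report for a run
#'
#' @param run A `"troutherm_run"`.
#' @return Character vector of report lines.
#' @export
render_report <- function(run) {
  m <- run$manifest
  lines <- c(
    "Thermal acclimation pipeline report",
    sprintf("seed: %s  config_hash: %s  package: troutherm %s",
            m$seed, m$config_hash, m$package_version),
    sprintf("respirometry fish: %d   CTmax fish: %d   background rate: %.5f mg/l/min",
            m$n_respirometry, m$n_ctm, m$blank_rate),
    sprintf("design: %d populations x %d acclimation temperatures",
            length(unique(run$design$population)),
            length(unique(run$design$acclimation_temp))),
    sprintf("adjusted means at reference mass %.1f g; alpha = %.2f; %d response analyses",
            m$reference_mass, m$alpha, length(run$analyses)),
    "")
  for (resp in names(run$analyses)) {
    a <- run$analyses[[resp]]
    tab <- a$fit$table
    line <- sprintf("%-16s %s:", resp, toupper(a$kind))
    for (trm in setdiff(tab$term, "Residuals")) {
      i <- which(tab$term == trm)
      line <- paste0(line, sprintf(" %s F=%.2f p=%.3g;", trm, tab$F[i], tab$p[i]))
    }
    lines <- c(lines, line)
  }
  qc <- run$resp_data$qc_flags
  n_flag <- sum(nzchar(qc))
  lines <- c(lines, "", sprintf("QC: %d of %d fish carry flags", n_flag, length(qc)))
  lines
}
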