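# Rendering latent truth profiles into the raw files the pipeline ingests.

#' Scheduled inflation times of the ambulatory monitor
#'
#' Enumerates cuff inflations over `[fit, fit + 24 h)`: the first inflation
#' is at fitting, and each next inflation follows after the interval of the
#' window (device-day / device-night) the current inflation falls in.
#'
#' @param config a [cohort_config()].
#' @return `POSIXct` vector of inflation times (UTC frame).
#' @export
abpm_schedule <- function(config) {
  fit <- parse_timestamp(paste0(config$fit_date, "T", config$fit_time, ":00"))
  day_start <- hm_to_minutes(config$device_day_start)
  day_end <- hm_to_minutes(config$device_day_end)
  end <- fit + 24 * 3600
  times <- c()
  t <- fit
  while (t < end) {
    times <- c(times, t)
    step <- if (in_clock_window(clock_minutes(t), day_start, day_end)) {
      config$day_interval
    } else {
      config$night_interval
    }
    t <- t + step * 60
  }
  .POSIXct(times, tz = "UTC")
}

profile_row <- function(profile) {
  if (is.data.frame(profile)) {
    stopifnot(nrow(profile) == 1)
    as.list(profile)
  } else {
    as.list(profile)
  }
}

#' Simulate one subject's 24-h ambulatory reading series
#'
#' Each scheduled reading equals the window-appropriate latent mean
#' (daytime mean inside the device-day window, daytime mean times the dip
#' ratio outside) plus independent Gaussian noise with the profile's
#' within-subject SD, rounded to integer mmHg. Missingness is then applied:
#' per-reading Bernoulli dropout and, with configured probability, a
#' contiguous "device removed" window.
#'
#' Uses the current RNG stream; seed externally (or via
#' [simulate_cohort_data()]) for reproducibility.
#'
#' @param profile one row of a `truth_cohort`.
#' @param config a [cohort_config()].
#' @param schedule optional precomputed [abpm_schedule()] (all subjects
#'   share it, so batch callers cache it).
#' @return data frame with columns `subject_id`, `timestamp` (ISO 8601),
#'   `sbp`, `dbp`.
#' @export
simulate_abpm_series <- function(profile, config, schedule = NULL) {
  p <- profile_row(profile)
  times <- if (is.null(schedule)) abpm_schedule(config) else schedule
  n <- length(times)
  day_start <- hm_to_minutes(config$device_day_start)
  day_end <- hm_to_minutes(config$device_day_end)
  is_day <- in_clock_window(clock_minutes(times), day_start, day_end)
  mu_sbp <- ifelse(is_day, p$day_sbp_true, p$day_sbp_true * p$dip_ratio)
  mu_dbp <- ifelse(is_day, p$day_dbp_true, p$day_dbp_true * p$dip_ratio)
  sbp <- round(mu_sbp + stats::rnorm(n, 0, p$reading_sd_sbp))
  dbp <- round(mu_dbp + stats::rnorm(n, 0, p$reading_sd_dbp))

  keep <- stats::runif(n) >= config$p_dropout
  if (stats::runif(1) < config$p_device_removal) {
    lo <- hm_to_minutes(config$removal_start_earliest)
    hi <- hm_to_minutes(config$removal_start_latest)
    span <- if (hi >= lo) hi - lo else hi + 1440 - lo
    start_clock <- (lo + stats::runif(1) * span) %% 1440
    dur_h <- stats::runif(1, config$removal_hours_min,
                          config$removal_hours_max)
    # place the removal clock time inside the monitoring span
    fit <- times[1]
    cand <- fit + (start_clock - clock_minutes(fit)) * 60
    if (cand < fit) cand <- cand + 24 * 3600
    keep <- keep & !(times >= cand & times < cand + dur_h * 3600)
  }
  data.frame(subject_id = p$subject_id,
             timestamp = format_timestamp(times[keep]),
             sbp = sbp[keep], dbp = dbp[keep],
             stringsAsFactors = FALSE)
}

#' Simulate one unattended office session (triplicate readings)
#'
#' Three automated readings taken 1 minute apart after 5 minutes of rest;
#' each equals the daytime latent mean plus the subject's office offset
#' plus independent noise, rounded to integer mmHg. The session mean is the
#' arithmetic mean of the three readings, matching the screening protocol.
#'
#' @param profile one row of a `truth_cohort`.
#' @return one-row data frame: `subject_id`, `sbp1`..`dbp3`, `mean_sbp`,
#'   `mean_dbp`.
#' @export
simulate_office_session <- function(profile) {
  p <- profile_row(profile)
  sbp <- round(p$day_sbp_true + p$office_offset_sbp +
                 stats::rnorm(3, 0, p$reading_sd_sbp))
  dbp <- round(p$day_dbp_true + p$office_offset_dbp +
                 stats::rnorm(3, 0, p$reading_sd_dbp))
  data.frame(subject_id = p$subject_id,
             sbp1 = sbp[1], dbp1 = dbp[1],
             sbp2 = sbp[2], dbp2 = dbp[2],
             sbp3 = sbp[3], dbp3 = dbp[3],
             mean_sbp = mean(sbp), mean_dbp = mean(dbp),
             stringsAsFactors = FALSE)
}

#' Simulate a full study data set
#'
#' Generates the cohort and renders every subject's ambulatory series and
#' office session. Fully deterministic for a fixed config.
#'
#' @param config a [cohort_config()].
#' @return list with elements `cohort` (truth), `readings` (long ABPM
#'   table) and `office` (one row per subject).
#' @export
simulate_cohort_data <- function(config) {
  cohort <- generate_cohort(config)  # seeds the RNG from config$seed
  sched <- abpm_schedule(config)
  series <- vector("list", nrow(cohort))
  office <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    series[[i]] <- simulate_abpm_series(cohort[i, ], config, sched)
    office[[i]] <- simulate_office_session(cohort[i, ])
  }
  list(cohort = cohort,
       readings = do.call(rbind, series),
       office = do.call(rbind, office))
}

#' Write a simulated study to the pipeline's raw-file formats
#'
#' Emits `abpm_readings.csv` (subject_id, timestamp, sbp, dbp),
#' `office.csv` (subject_id, sbp1..dbp3), `subjects.csv` (covariates and
#' medication flag) and `truth.csv` (all latent fields; consumed only by
#' tests, never by the pipeline). Round-trips losslessly through
#' [parse_readings()] / [read_office_sessions()] / [read_subjects()].
#'
#' @param sim result of [simulate_cohort_data()].
#' @param directory output directory (created if absent).
#' @return invisibly, the named vector of file paths.
#' @export
write_cohort_files <- function(sim, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory, call. = FALSE)
  }
  paths <- c(readings = file.path(directory, "abpm_readings.csv"),
             office = file.path(directory, "office.csv"),
             subjects = file.path(directory, "subjects.csv"),
             truth = file.path(directory, "truth.csv"))
  utils::write.csv(sim$readings, paths[["readings"]], row.names = FALSE)
  utils::write.csv(sim$office[, c("subject_id", "sbp1", "dbp1", "sbp2",
                                  "dbp2", "sbp3", "dbp3")],
                   paths[["office"]], row.names = FALSE)
  subj_cols <- c("subject_id", "age", "sex", "site", "bmi", "diabetes",
                 "smoker", "on_medication")
  utils::write.csv(sim$cohort[, subj_cols], paths[["subjects"]],
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sim$cohort), paths[["truth"]],
                   row.names = FALSE)
  invisible(paths)
}
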