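#' Configuration for the synthetic circadian-BP cohort generator
#'
#' Bundles every knob of the simulated world: cohort size, the latent
#' blood-pressure mixture (confirmed-hypertensive prevalence and the
#' normotensive/hypertensive 24-h distributions), nocturnal dipping,
#' office-offset phenotype mixture (white-coat / masked), within-subject
#' reading noise, the device inflation schedule, and missingness.
#'
#' The latent model is two-level: each subject has a daytime mean (over the
#' device-day window) and a nighttime mean obtained by multiplying with a
#' per-subject dip ratio. The time-weighted 24-h mean implied by these
#' latents is `(H_day * day + H_night * day * dip) / 24` where `H_day` and
#' `H_night` are the device-day/night window lengths in hours. Subjects are
#' drawn as a two-component mixture on this implied 24-h scale so that the
#' configured prevalence of confirmed hypertension (implied 24-h mean
#' >= 130/80 mmHg) holds exactly in expectation: hypertensive subjects draw
#' implied systolic from a normal truncated at 130 from below; normotensive
#' subjects draw systolic truncated below 130 and diastolic below 80.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the config.
#' @param prev_hypertension target prevalence of confirmed hypertension
#'   (implied 24-h mean >= 130/80 mmHg).
#' @param htn_sbp24_mean,htn_sbp24_sd,htn_dbp24_mean,htn_dbp24_sd implied
#'   24-h distribution for the hypertensive component (mmHg); systolic is
#'   truncated at 130 from below.
#' @param nt_sbp24_mean,nt_sbp24_sd,nt_dbp24_mean,nt_dbp24_sd implied 24-h
#'   distribution for the normotensive component, truncated below 130/80.
#' @param dip_mean,dip_sd,dip_lower,dip_upper per-subject night/day dip
#'   ratio distribution (truncated normal).
#' @param p_white_coat,p_masked mixture weights of the positive (white-coat)
#'   and negative (masked) office-offset components; the remainder gets a
#'   zero-centred offset.
#' @param offset_wc_mean,offset_wc_sd,offset_masked_mean,offset_masked_sd,offset_base_sd
#'   systolic office-offset component parameters (mmHg); the diastolic
#'   offset is 0.6 x systolic plus independent jitter.
#' @param offset_dbp_jitter_sd SD of the per-subject diastolic-offset
#'   jitter around 0.6 x the systolic offset (mmHg).
#' @param reading_sd_sbp_mean,reading_sd_sbp_sd,reading_sd_dbp_mean,reading_sd_dbp_sd
#'   per-subject within-subject reading noise SD distribution (mmHg,
#'   truncated at >= 0.5 unless the mean is 0, in which case all SDs are 0).
#' @param p_dropout per-reading Bernoulli dropout probability (MCAR).
#' @param p_device_removal probability that a subject removes the device for
#'   one contiguous window (typically overnight).
#' @param removal_start_earliest,removal_start_latest clock times ("HH:MM")
#'   between which the removal window starts (may wrap midnight).
#' @param removal_hours_min,removal_hours_max removal duration range, hours.
#' @param day_interval,night_interval inflation intervals in minutes during
#'   the device-day and device-night windows.
#' @param device_day_start,device_day_end device-day window ("HH:MM"); the
#'   20-minute schedule applies in `[start, end)`, the 40-minute schedule
#'   outside. Deliberately distinct from the 10:00-20:00 / 00:00-06:00
#'   analysis windows.
#' @param fit_time clock time ("HH:MM") the monitor is fitted; readings run
#'   for 24 h from there.
#' @param fit_date calendar date of fitting (all subjects share it).
#' @param p_medicated probability of self-reported antihypertensive use
#'   (flag only; the latent mixture is unaffected so the configured
#'   prevalence holds cohort-wide).
#' @param p_female,p_diabetes,p_smoker covariate prevalences.
#' @param sites character vector of site labels, sampled uniformly.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [simulate_cohort_data()]
#' @export
cohort_config <- function(n_subjects = 1291,
                          seed = 1L,
                          prev_hypertension = 0.35,
                          htn_sbp24_mean = 142, htn_sbp24_sd = 12,
                          htn_dbp24_mean = 86, htn_dbp24_sd = 8,
                          nt_sbp24_mean = 112, nt_sbp24_sd = 10,
                          nt_dbp24_mean = 70, nt_dbp24_sd = 6,
                          dip_mean = 0.9, dip_sd = 0.07,
                          dip_lower = 0.65, dip_upper = 1.15,
                          p_white_coat = 0.15, p_masked = 0.40,
                          offset_wc_mean = 15, offset_wc_sd = 5,
                          offset_masked_mean = -32, offset_masked_sd = 8,
                          offset_base_sd = 4,
                          offset_dbp_jitter_sd = 2,
                          reading_sd_sbp_mean = 9, reading_sd_sbp_sd = 2,
                          reading_sd_dbp_mean = 7, reading_sd_dbp_sd = 1.5,
                          p_dropout = 0.10,
                          p_device_removal = 0.20,
                          removal_start_earliest = "21:00",
                          removal_start_latest = "01:00",
                          removal_hours_min = 4, removal_hours_max = 8,
                          day_interval = 20, night_interval = 40,
                          device_day_start = "06:00",
                          device_day_end = "22:00",
                          fit_time = "09:00",
                          fit_date = "2017-06-01",
                          p_medicated = 0.06,
                          p_female = 0.55,
                          p_diabetes = 0.02,
                          p_smoker = 0.10,
                          sites = c("Kilifi", "Kirinyaga", "Webuye")) {
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid cohort_config field `%s`: %s", field, why),
         call. = FALSE)
  }
  num1 <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      fail(field, "must be a single non-missing number")
    }
    v
  }
  if (num1("n_subjects") < 1) fail("n_subjects", "must be >= 1")
  num1("seed")
  for (f in c("prev_hypertension", "p_white_coat", "p_masked", "p_dropout",
              "p_device_removal", "p_medicated", "p_female", "p_diabetes",
              "p_smoker")) {
    v <- num1(f)
    if (v < 0 || v > 1) fail(f, "must be a probability in [0, 1]")
  }
  if (cfg$p_white_coat + cfg$p_masked > 1) {
    fail("p_white_coat", "p_white_coat + p_masked must not exceed 1")
  }
  for (f in c("day_interval", "night_interval")) {
    if (num1(f) <= 0) fail(f, "must be a positive number of minutes")
  }
  for (f in c("htn_sbp24_sd", "htn_dbp24_sd", "nt_sbp24_sd", "nt_dbp24_sd",
              "dip_sd", "offset_wc_sd", "offset_masked_sd", "offset_base_sd",
              "offset_dbp_jitter_sd",
              "reading_sd_sbp_mean", "reading_sd_dbp_mean")) {
    if (num1(f) < 0) fail(f, "must be non-negative")
  }
  if (num1("dip_lower") <= 0) fail("dip_lower", "dip ratio must stay > 0")
  if (num1("dip_upper") <= cfg$dip_lower) {
    fail("dip_upper", "must exceed dip_lower")
  }
  if (num1("removal_hours_min") < 0 ||
      num1("removal_hours_max") < cfg$removal_hours_min) {
    fail("removal_hours_max", "removal duration range is empty")
  }
  for (f in c("device_day_start", "device_day_end", "fit_time",
              "removal_start_earliest", "removal_start_latest")) {
    v <- cfg[[f]]
    if (!is.character(v) || length(v) != 1 ||
        !grepl("^[0-2]?[0-9]:[0-5][0-9]$", v)) {
      fail(f, "must be a clock time \"HH:MM\"")
    }
  }
  if (hm_to_minutes(cfg$device_day_start) >=
      hm_to_minutes(cfg$device_day_end)) {
    fail("device_day_end", "device-day window must not wrap midnight")
  }
  if (!is.character(cfg$sites) || length(cfg$sites) < 1) {
    fail("sites", "must be a non-empty character vector")
  }
  invisible(cfg)
}

# device-day / device-night window lengths in hours
device_hours <- function(config) {
  day <- (hm_to_minutes(config$device_day_end) -
            hm_to_minutes(config$device_day_start)) / 60
  c(day = day, night = 24 - day)
}

#' Closed-form time-weighted 24-h mean implied by latent profiles
#'
#' For a two-level latent profile the duration-weighted 24-h mean is
#' `(H_day * day + H_night * day * dip) / 24` with window lengths taken
#' from the device schedule in `config`.
#'
#' @param cohort a `truth_cohort` data frame from [generate_cohort()].
#' @param config the [cohort_config()] used to generate it.
#' @return data frame with columns `sbp24`, `dbp24` (mmHg).
#' @export
truth_24h_mean <- function(cohort, config) {
  h <- device_hours(config)
  w <- (h[["day"]] + h[["night"]] * cohort$dip_ratio) / 24
  data.frame(sbp24 = cohort$day_sbp_true * w,
             dbp24 = cohort$day_dbp_true * w)
}
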