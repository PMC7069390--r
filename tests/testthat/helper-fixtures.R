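# Shared fixture builders and independent oracles.

# hand-built abpm_record from "HH:MM" clock times on a fixed date
make_record <- function(times_hm, sbp, dbp, id = "X1", date = "2020-01-01",
                        fit_hm = NULL) {
  # times after the first that are clock-earlier roll to the next day
  mins <- hm_to_minutes_h(times_hm)
  day <- cumsum(c(0, diff(mins) < 0))
  t <- parse_timestamp(paste0(date, "T", times_hm, ":00")) + day * 86400
  fit <- if (is.null(fit_hm)) NULL else
    parse_timestamp(paste0(date, "T", fit_hm, ":00"))
  abpmscreen:::new_abpm_record(id, t, sbp, dbp, fit_time = fit)
}

hm_to_minutes_h <- function(x) {
  vapply(strsplit(x, ":", fixed = TRUE),
         function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), 0)
}

# independent loop-based oracle for the midpoint-interval weighted mean:
# integrates the nearest-reading step function over the 24-h span
oracle_weighted_mean <- function(times, values, span_start, span_end) {
  s <- as.numeric(times)
  total <- 0
  weight <- 0
  for (i in seq_along(s)) {
    lo <- if (i == 1) as.numeric(span_start) else (s[i - 1] + s[i]) / 2
    hi <- if (i == length(s)) as.numeric(span_end) else (s[i] + s[i + 1]) / 2
    total <- total + values[i] * (hi - lo)
    weight <- weight + (hi - lo)
  }
  total / weight
}

# exhaustive pair-counting oracle for the empirical AUC
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# two-sided exact McNemar p by direct pmf enumeration
oracle_mcnemar_exact <- function(b, c) {
  n <- b + c
  pmf <- stats::dbinom(0:n, n, 0.5)
  sum(pmf[pmf <= stats::dbinom(b, n, 0.5) + 1e-12])
}

# quick cohort -> raw files on disk; returns the directory
write_sim <- function(config) {
  d <- tempfile("cohort")
  write_cohort_files(simulate_cohort_data(config), d)
  d
}

run_quiet <- function(config, dir) {
  suppressWarnings(run_pipeline(config,
                                file.path(dir, "abpm_readings.csv"),
                                file.path(dir, "office.csv"),
                                file.path(dir, "subjects.csv")))
}

# a small noise-free world: deterministic pressures, no missingness;
# named overrides in ... win over the noise-free defaults
noisefree_config <- function(n = 50, seed = 5, ...) {
  defaults <- list(n_subjects = n, seed = seed,
                   reading_sd_sbp_mean = 0, reading_sd_sbp_sd = 0,
                   reading_sd_dbp_mean = 0, reading_sd_dbp_sd = 0,
                   offset_wc_sd = 0, offset_masked_sd = 0,
                   offset_base_sd = 0, offset_dbp_jitter_sd = 0,
                   p_white_coat = 0, p_masked = 0,
                   p_dropout = 0, p_device_removal = 0, p_medicated = 0)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}
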