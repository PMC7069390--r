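# Quality control and window / time-weighted summaries of one ABPM record.
#
# The completeness rule follows the IDACO criteria: a record is usable when
# it holds at least 10 readings in the daytime analysis window (10:00-20:00)
# and at least 5 in the nighttime window (00:00-06:00). Both windows are
# half-open [start, end) so a reading stamped exactly at the end bound
# falls outside, and they are disjoint, so no reading is double-counted.

DAY_WINDOW <- c("10:00", "20:00")
NIGHT_WINDOW <- c("00:00", "06:00")

#' Completeness-based quality control of an ambulatory record
#'
#' @param record an `abpm_record`.
#' @param day_window,night_window clock windows `c(start, end)` in "HH:MM",
#'   half-open.
#' @param min_day,min_night minimum reading counts (defaults 10 and 5, the
#'   IDACO completeness criteria).
#' @return list with `n_day`, `n_night`, `qc_pass`.
#' @export
quality_filter <- function(record, day_window = DAY_WINDOW,
                           night_window = NIGHT_WINDOW,
                           min_day = 10, min_night = 5) {
  mins <- clock_minutes(record$times)
  n_day <- sum(in_clock_window(mins, hm_to_minutes(day_window[1]),
                               hm_to_minutes(day_window[2])))
  n_night <- sum(in_clock_window(mins, hm_to_minutes(night_window[1]),
                                 hm_to_minutes(night_window[2])))
  list(n_day = n_day, n_night = n_night,
       qc_pass = n_day >= min_day && n_night >= min_night)
}

#' Unweighted mean over a clock-time window
#'
#' Arithmetic mean of all readings whose clock time falls in the half-open
#' window. An empty window yields `NA` means with `n = 0` (flagged missing,
#' never zero).
#'
#' @param record an `abpm_record`.
#' @param window `c(start, end)` clock times "HH:MM".
#' @return list with `n`, `sbp`, `dbp`.
#' @export
window_mean <- function(record, window) {
  mins <- clock_minutes(record$times)
  i <- in_clock_window(mins, hm_to_minutes(window[1]),
                       hm_to_minutes(window[2]))
  if (!any(i)) return(list(n = 0L, sbp = NA_real_, dbp = NA_real_))
  list(n = sum(i), sbp = mean(record$sbp[i]), dbp = mean(record$dbp[i]))
}

# midpoint-interval weights over the record's 24-h span [fit, fit + 24 h]:
# each reading represents the stretch from the midpoint with its
# predecessor to the midpoint with its successor; the first and last
# stretches are clipped at the span ends
interval_weights <- function(times, span_start, span_end) {
  s <- as.numeric(times)
  mids <- (s[-1] + s[-length(s)]) / 2
  bounds <- c(as.numeric(span_start), mids, as.numeric(span_end))
  diff(bounds)
}

#' Time-weighted 24-hour mean
#'
#' Weights each reading by the length of the interval it represents, which
#' accounts for the sparser nighttime sampling schedule (40-minute versus
#' 20-minute inflation intervals). Two modes:
#'
#' * `"interval"` (default): midpoint-interval weighting. Reading *i*'s
#'   weight runs from the midpoint with its predecessor to the midpoint
#'   with its successor; the first and last intervals are clipped at the
#'   record's 24-h span (fit time to fit time + 24 h). Readings after the
#'   24-h span are dropped first.
#' * `"hourly"`: mean of per-clock-hour means (a common device-software
#'   alternative).
#'
#' Equally spaced readings make the interval mode collapse to the plain
#' arithmetic mean.
#'
#' @param record an `abpm_record`.
#' @param mode `"interval"` or `"hourly"`.
#' @return list with `n`, `sbp`, `dbp` (`NA` with a warning-free flag when
#'   fewer than 2 readings are available).
#' @export
weighted_24h_mean <- function(record, mode = c("interval", "hourly")) {
  mode <- match.arg(mode)
  span_start <- record$fit_time
  span_end <- span_start + 24 * 3600
  keep <- record$times >= span_start & record$times <= span_end
  times <- record$times[keep]
  sbp <- record$sbp[keep]
  dbp <- record$dbp[keep]
  if (length(times) < 2) {
    return(list(n = length(times), sbp = NA_real_, dbp = NA_real_))
  }
  if (mode == "interval") {
    w <- interval_weights(times, span_start, span_end)
    list(n = length(times),
         sbp = sum(w * sbp) / sum(w),
         dbp = sum(w * dbp) / sum(w))
  } else {
    hr <- floor(clock_minutes(times) / 60)
    list(n = length(times),
         sbp = mean(tapply(sbp, hr, mean)),
         dbp = mean(tapply(dbp, hr, mean)))
  }
}

#' Mean of an unattended office session
#'
#' The screening measurement is the average of the three automated
#' readings. Readings are valid when both pressures are present and
#' `sbp > dbp`. With all three valid the session is `complete`; with two it
#' is averaged but flagged; with fewer the means are `NA` and the subject
#' is excluded from the primary analysis downstream.
#'
#' @param sbp,dbp numeric vectors of up to three readings (NA = missing).
#' @param subject_id optional id carried through.
#' @return one-row data frame: `subject_id`, `n_readings`, `mean_sbp`,
#'   `mean_dbp`, `complete`, `usable`.
#' @export
office_mean <- function(sbp, dbp, subject_id = NA_character_) {
  valid <- is.finite(sbp) & is.finite(dbp) & sbp > dbp
  n <- sum(valid)
  data.frame(subject_id = subject_id,
             n_readings = n,
             mean_sbp = if (n >= 2) mean(sbp[valid]) else NA_real_,
             mean_dbp = if (n >= 2) mean(dbp[valid]) else NA_real_,
             complete = n == 3,
             usable = n >= 2,
             stringsAsFactors = FALSE)
}

#' Summarize ambulatory records into per-subject analysis rows
#'
#' Applies [quality_filter()], the daytime/nighttime [window_mean()]s and
#' the [weighted_24h_mean()] to every record.
#'
#' @param records list of `abpm_record` (from [parse_readings()]).
#' @param weighting_mode passed to [weighted_24h_mean()].
#' @param day_window,night_window analysis windows, "HH:MM".
#' @return data frame: `subject_id`, `n_day`, `n_night`, `qc_pass`,
#'   `day_sbp`, `day_dbp`, `night_sbp`, `night_dbp`, `wt24_sbp`, `wt24_dbp`.
#' @export
summarize_abpm <- function(records, weighting_mode = "interval",
                           day_window = DAY_WINDOW,
                           night_window = NIGHT_WINDOW) {
  if (length(records) == 0) {
    return(data.frame(subject_id = character(), n_day = integer(),
                      n_night = integer(), qc_pass = logical(),
                      day_sbp = numeric(), day_dbp = numeric(),
                      night_sbp = numeric(), night_dbp = numeric(),
                      wt24_sbp = numeric(), wt24_dbp = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(records, function(r) {
    qc <- quality_filter(r, day_window, night_window)
    d <- window_mean(r, day_window)
    n <- window_mean(r, night_window)
    w <- weighted_24h_mean(r, weighting_mode)
    data.frame(subject_id = r$subject_id,
               n_day = qc$n_day, n_night = qc$n_night,
               qc_pass = qc$qc_pass,
               day_sbp = d$sbp, day_dbp = d$dbp,
               night_sbp = n$sbp, night_dbp = n$dbp,
               wt24_sbp = w$sbp, wt24_dbp = w$dbp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
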