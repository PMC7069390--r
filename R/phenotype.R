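# Screen / reference status and the four-category hypertension phenotype.
#
# All cutoffs use the guideline OR rule with a non-strict inequality: a
# subject is positive when systolic >= systolic cutoff OR diastolic >=
# diastolic cutoff.

#' Construct a systolic/diastolic threshold pair
#'
#' @param sbp_cut,dbp_cut cutoffs in mmHg (`sbp_cut > dbp_cut > 0`).
#' @param label display label; defaults to `"sbp/dbp"`.
#' @return object of class `threshold_pair`.
#' @export
threshold_pair <- function(sbp_cut, dbp_cut,
                           label = sprintf("%g/%g", sbp_cut, dbp_cut)) {
  if (!(is.numeric(sbp_cut) && is.numeric(dbp_cut) &&
          sbp_cut > dbp_cut && dbp_cut > 0)) {
    stop("threshold must satisfy sbp_cut > dbp_cut > 0", call. = FALSE)
  }
  structure(list(sbp_cut = sbp_cut, dbp_cut = dbp_cut, label = label),
            class = "threshold_pair")
}

#' Parse `"130/80,135/85"`-style threshold strings
#'
#' @param x character vector (possibly comma-separated) of `"SBP/DBP"`.
#' @return list of [threshold_pair()]s.
#' @export
parse_thresholds <- function(x) {
  parts <- unlist(strsplit(x, ",", fixed = TRUE))
  lapply(trimws(parts), function(p) {
    v <- suppressWarnings(as.numeric(strsplit(p, "/", fixed = TRUE)[[1]]))
    if (length(v) != 2 || anyNA(v)) {
      stop("cannot parse threshold: ", p, call. = FALSE)
    }
    threshold_pair(v[1], v[2])
  })
}

# the three international screen cutoffs evaluated by default
default_thresholds <- function() {
  list(threshold_pair(130, 80), threshold_pair(135, 85),
       threshold_pair(140, 90))
}

# reference-standard cutoffs: 24-h 130/80 (ESH confirmed hypertension),
# daytime 135/85 (awake ambulatory hypertension), nocturnal 120/70
reference_cutoffs <- function(reference) {
  switch(reference,
         "24h" = threshold_pair(130, 80),
         daytime = threshold_pair(135, 85),
         nocturnal = threshold_pair(120, 70),
         stop("unknown reference standard: ", reference, call. = FALSE))
}

#' Screen-positivity of an office measurement
#'
#' Positive when mean systolic >= the systolic cutoff OR mean diastolic >=
#' the diastolic cutoff (non-strict).
#'
#' @param mean_sbp,mean_dbp office session means, mmHg (vectorized).
#' @param threshold a [threshold_pair()].
#' @return logical vector (`NA` where the mean is missing).
#' @export
screen_status <- function(mean_sbp, mean_dbp, threshold) {
  stopifnot(inherits(threshold, "threshold_pair"))
  mean_sbp >= threshold$sbp_cut | mean_dbp >= threshold$dbp_cut
}

#' Reference hypertension status from an ambulatory summary
#'
#' Applies the OR rule at the reference standard's cutoff pair to the
#' matching summary means: `"24h"` uses 130/80 on the time-weighted 24-h
#' means, `"daytime"` uses 135/85 on the daytime-window means, and
#' `"nocturnal"` uses 120/70 on the nighttime-window means. Summaries that
#' failed quality control yield `NA` (excluded) unless
#' `allow_qc_failures = TRUE` (the sensitivity analysis).
#'
#' @param summaries data frame from [summarize_abpm()] (vectorized over
#'   rows).
#' @param reference one of `"24h"`, `"daytime"`, `"nocturnal"`.
#' @param allow_qc_failures evaluate QC-failed records too.
#' @return logical vector.
#' @export
reference_status <- function(summaries, reference = c("24h", "daytime",
                                                      "nocturnal"),
                             allow_qc_failures = FALSE) {
  reference <- match.arg(reference)
  cut <- reference_cutoffs(reference)
  cols <- switch(reference,
                 "24h" = c("wt24_sbp", "wt24_dbp"),
                 daytime = c("day_sbp", "day_dbp"),
                 nocturnal = c("night_sbp", "night_dbp"))
  status <- summaries[[cols[1]]] >= cut$sbp_cut |
    summaries[[cols[2]]] >= cut$dbp_cut
  if (!allow_qc_failures) status[!summaries$qc_pass] <- NA
  status
}

#' Four-category hypertension phenotype
#'
#' Cross of screen and confirmed status: sustained (+/+), white-coat
#' (+/-), masked (-/+), normotensive (-/-). The four categories are
#' mutually exclusive and exhaustive over subjects with both statuses
#' defined.
#'
#' @param screen,confirmed logical vectors of equal length.
#' @return factor with levels `sustained`, `white_coat`, `masked`,
#'   `normotensive`.
#' @export
phenotype <- function(screen, confirmed) {
  if (length(screen) != length(confirmed)) {
    stop("screen and confirmed must have equal length", call. = FALSE)
  }
  lab <- ifelse(screen & confirmed, "sustained",
                ifelse(screen & !confirmed, "white_coat",
                       ifelse(!screen & confirmed, "masked",
                              "normotensive")))
  factor(lab, levels = c("sustained", "white_coat", "masked",
                         "normotensive"))
}

#' Nocturnal dipping status
#'
#' A subject is a nondipper when nighttime systolic fails to fall below
#' `ratio` (default 0.9, i.e. a less-than-10% nocturnal decline) times the
#' daytime systolic. Descriptive output only; no accuracy measure uses it.
#'
#' @param night_sbp,day_sbp window means, mmHg (vectorized).
#' @param ratio nondipping cutoff on night/day (default 0.9).
#' @return factor with levels `dipper`, `nondipper`.
#' @export
dipping_status <- function(night_sbp, day_sbp, ratio = 0.9) {
  factor(ifelse(night_sbp / day_sbp > ratio, "nondipper", "dipper"),
         levels = c("dipper", "nondipper"))
}

#' Classify a cohort at each configured threshold
#'
#' Joins office means to ambulatory summaries and evaluates screen status,
#' the reference statuses and the phenotype at every threshold.
#'
#' @param summaries data frame from [summarize_abpm()].
#' @param office data frame from [read_office_sessions()].
#' @param thresholds list of [threshold_pair()]s.
#' @param reference reference standard for the phenotype (see
#'   [reference_status()]).
#' @param allow_qc_failures passed to [reference_status()].
#' @return long data frame, one row per subject x threshold:
#'   `subject_id`, `threshold_label`, `screen_positive`, `confirmed_24h`,
#'   `confirmed_daytime`, `nocturnal_htn`, `phenotype`, `dipping`.
#' @export
classify_cohort <- function(summaries, office,
                            thresholds = default_thresholds(),
                            reference = "24h",
                            allow_qc_failures = FALSE) {
  m <- merge(summaries, office, by = "subject_id")
  conf24 <- reference_status(m, "24h", allow_qc_failures)
  confday <- reference_status(m, "daytime", allow_qc_failures)
  nocturnal <- reference_status(m, "nocturnal", allow_qc_failures)
  confirmed <- if (reference == "daytime") confday else conf24
  dip <- dipping_status(m$night_sbp, m$day_sbp)
  out <- lapply(thresholds, function(th) {
    scr <- screen_status(m$mean_sbp, m$mean_dbp, th)
    data.frame(subject_id = m$subject_id,
               threshold_label = th$label,
               screen_positive = scr,
               confirmed_24h = conf24,
               confirmed_daytime = confday,
               nocturnal_htn = nocturnal,
               phenotype = phenotype(scr, confirmed),
               dipping = dip,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
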