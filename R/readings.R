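# Ingest of raw readings and office-session files.

new_abpm_record <- function(subject_id, times, sbp, dbp, fit_time = NULL) {
  ord <- order(times)
  times <- times[ord]
  if (anyDuplicated(as.numeric(times))) {
    stop("duplicate timestamps for subject ", subject_id, call. = FALSE)
  }
  structure(list(subject_id = subject_id,
                 fit_time = if (is.null(fit_time)) times[1] else fit_time,
                 times = times, sbp = sbp[ord], dbp = dbp[ord]),
            class = "abpm_record")
}

#' @export
print.abpm_record <- function(x, ...) {
  cat(sprintf("<abpm_record %s: %d readings, %s .. %s>\n", x$subject_id,
              length(x$times), format_timestamp(x$times[1]),
              format_timestamp(x$times[length(x$times)])))
  invisible(x)
}

#' Parse an ambulatory readings file into per-subject records
#'
#' Reads a CSV with columns `subject_id`, `timestamp` (ISO 8601), `sbp`,
#' `dbp`; groups rows by subject and sorts by time. Rows with an
#' unparseable timestamp or with `dbp >= sbp` are excluded with a warning
#' that reports their line numbers (header = line 1). Optional plausibility
#' filtering (off by default, since screening devices report artefacts
#' verbatim) additionally drops readings outside `sbp_bounds` /
#' `dbp_bounds` or with pulse pressure below `min_pulse_pressure`.
#'
#' @param file path to the readings CSV.
#' @param plausibility apply plausibility bounds (default `FALSE`).
#' @param sbp_bounds,dbp_bounds inclusive plausibility ranges, mmHg.
#' @param min_pulse_pressure minimum `sbp - dbp`, mmHg.
#' @return named list of `abpm_record` objects (possibly empty).
#' @export
parse_readings <- function(file, plausibility = FALSE,
                           sbp_bounds = c(60, 260), dbp_bounds = c(40, 160),
                           min_pulse_pressure = 10) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character"))
  need <- c("subject_id", "timestamp", "sbp", "dbp")
  if (!all(need %in% names(raw))) {
    stop("readings file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) return(list())
  line_no <- seq_len(nrow(raw)) + 1L
  t <- parse_timestamp(raw$timestamp)

  bad_time <- is.na(t)
  bad_pp <- !bad_time & (!is.finite(raw$sbp) | !is.finite(raw$dbp) |
                           raw$sbp <= raw$dbp)
  bad <- bad_time | bad_pp
  if (plausibility) {
    implaus <- !bad & (raw$sbp < sbp_bounds[1] | raw$sbp > sbp_bounds[2] |
                         raw$dbp < dbp_bounds[1] | raw$dbp > dbp_bounds[2] |
                         raw$sbp - raw$dbp < min_pulse_pressure)
    bad <- bad | implaus
  }
  if (any(bad)) {
    warning(sprintf("excluded %d malformed reading row(s) at line(s) %s",
                    sum(bad), paste(line_no[bad], collapse = ", ")),
            call. = FALSE)
  }
  keep <- raw[!bad, , drop = FALSE]
  t <- t[!bad]
  idx <- split(seq_len(nrow(keep)), keep$subject_id)
  idx <- idx[unique(keep$subject_id)]  # preserve first-appearance order
  records <- lapply(names(idx), function(id) {
    i <- idx[[id]]
    new_abpm_record(id, t[i], keep$sbp[i], keep$dbp[i])
  })
  names(records) <- names(idx)
  records
}

#' Read office-session files (triplicate unattended readings)
#'
#' Reads a CSV with columns `subject_id`, `sbp1`, `dbp1`, `sbp2`, `dbp2`,
#' `sbp3`, `dbp3` (blank cells = missing reading) and computes each
#' session's mean via [office_mean()].
#'
#' @param file path to the office CSV.
#' @return data frame: `subject_id`, `n_readings`, `mean_sbp`, `mean_dbp`,
#'   `complete` (all three readings valid), `usable` (at least two).
#' @export
read_office_sessions <- function(file) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character"))
  need <- c("subject_id", paste0(rep(c("sbp", "dbp"), 3), rep(1:3, each = 2)))
  if (!all(need %in% names(raw))) {
    stop("office file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(raw)), function(i) {
    sbp <- as.numeric(raw[i, c("sbp1", "sbp2", "sbp3")])
    dbp <- as.numeric(raw[i, c("dbp1", "dbp2", "dbp3")])
    office_mean(sbp, dbp, subject_id = raw$subject_id[i])
  }))
  rownames(out) <- NULL
  out
}

#' Read the subject covariates file
#'
#' @param file CSV with columns `subject_id`, `age`, `sex`, `site`, `bmi`,
#'   `diabetes`, `smoker`, `on_medication`.
#' @return data frame with logical medication/diabetes/smoker flags.
#' @export
read_subjects <- function(file) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE,
                         colClasses = c(subject_id = "character"))
  need <- c("subject_id", "age", "sex", "site", "bmi", "diabetes",
            "smoker", "on_medication")
  if (!all(need %in% names(raw))) {
    stop("subjects file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  for (f in c("diabetes", "smoker", "on_medication")) {
    raw[[f]] <- as.logical(raw[[f]])
  }
  raw
}
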