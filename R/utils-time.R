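# Timestamp handling. All timestamps are treated as local clock time and
# parsed in a fixed UTC frame so that arithmetic is DST-free and
# deterministic across machines.

#' Parse ISO 8601 timestamps
#'
#' Accepts `"YYYY-MM-DDTHH:MM:SS"` or `"YYYY-MM-DD HH:MM:SS"` (seconds
#' optional). Returns `POSIXct` in UTC; elements that fail to parse are `NA`.
#'
#' @param x character vector of timestamps.
#' @return `POSIXct` vector, UTC.
#' @export
parse_timestamp <- function(x) {
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  missing_sec <- is.na(out) & !is.na(x)
  if (any(missing_sec)) {
    out[missing_sec] <- as.POSIXct(x[missing_sec], tz = "UTC",
                                   format = "%Y-%m-%d %H:%M")
  }
  out
}

#' Minutes past midnight of a timestamp
#'
#' @param t `POSIXct` vector.
#' @return numeric vector in `[0, 1440)`.
#' @export
clock_minutes <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour * 60 + lt$min + lt$sec / 60
}

#' Test clock-time membership in a half-open window
#'
#' Windows are half-open `[start, end)` in minutes past midnight and may
#' wrap midnight (e.g. `start = 1320, end = 360` for 22:00-06:00).
#'
#' @param minutes numeric vector of clock minutes.
#' @param start,end window bounds in minutes past midnight.
#' @return logical vector.
#' @export
in_clock_window <- function(minutes, start, end) {
  if (start < end) {
    minutes >= start & minutes < end
  } else {
    minutes >= start | minutes < end
  }
}

format_timestamp <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

# hh:mm string -> minutes past midnight
hm_to_minutes <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), 0)
}
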