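#' Timestamps and intervals on the simulated clock
#'
#' Telemetry timestamps use a compact dialect, `YYYY-MM-DD-HHMMSS` at second
#' resolution, with a minute-resolution short form `YYYY-MM-DD-HHMM` used for
#' message-receipt times (mobile handsets do not report sub-minute receipt
#' times, so the receipt stamp is deliberately coarse). Internally an instant
#' is a number of seconds since the Unix epoch (UTC); the whole pipeline runs
#' on a simulated clock at one-second resolution, so instants are always whole
#' seconds.
#'
#' @name timestamps
NULL

#' Parse a telemetry timestamp
#'
#' Accepts the compact dialect `YYYY-MM-DD-HHMMSS` (second resolution) or
#' `YYYY-MM-DD-HHMM` (minute resolution, flagged as coarse), plus ISO-8601
#' `YYYY-MM-DD HH:MM:SS` / `YYYY-MM-DDTHH:MM:SS` as input aliases.
#'
#' @param text character vector of timestamps.
#' @return an `instant` object: numeric seconds since epoch (UTC) with a
#'   logical `coarse` attribute marking minute-resolution values.
#' @examples
#' parse_timestamp("2016-11-04-173424")
#' parse_timestamp("2016-11-04-1734")   # coarse, minute resolution
#' @export
parse_timestamp <- function(text) {
  stopifnot(is.character(text))
  n <- length(text)
  secs <- numeric(n)
  coarse <- logical(n)
  for (i in seq_len(n)) {
    x <- text[[i]]
    # normalise ISO-8601 aliases to the compact dialect
    if (grepl("^\\d{4}-\\d{2}-\\d{2}[T ]\\d{2}:\\d{2}:\\d{2}$", x)) {
      x <- paste0(substr(x, 1, 10), "-", gsub(":", "", substr(x, 12, 19)))
    }
    m <- regmatches(x, regexec(
      "^(\\d{4})-(\\d{2})-(\\d{2})-(\\d{2})(\\d{2})(\\d{2})?$", x))[[1]]
    if (length(m) == 0) {
      stop("malformed timestamp '", x,
           "': expected YYYY-MM-DD-HHMMSS or YYYY-MM-DD-HHMM", call. = FALSE)
    }
    year <- as.integer(m[2]); month <- as.integer(m[3]); day <- as.integer(m[4])
    hour <- as.integer(m[5]); minute <- as.integer(m[6])
    second <- if (m[7] == "") NA_integer_ else as.integer(m[7])
    if (month < 1 || month > 12)
      stop("malformed timestamp '", x, "': month out of range", call. = FALSE)
    if (hour > 23)
      stop("malformed timestamp '", x, "': hour out of range", call. = FALSE)
    if (minute > 59)
      stop("malformed timestamp '", x, "': minute out of range", call. = FALSE)
    if (!is.na(second) && second > 59)
      stop("malformed timestamp '", x, "': second out of range", call. = FALSE)
    t <- as.POSIXct(sprintf("%04d-%02d-%02d %02d:%02d:%02d",
                            year, month, day, hour, minute,
                            ifelse(is.na(second), 0L, second)),
                    tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
    if (is.na(t))
      stop("malformed timestamp '", x, "': day out of range for month",
           call. = FALSE)
    # reject normalised dates (e.g. Feb 30 silently rolling over)
    if (format(t, "%d", tz = "UTC") != sprintf("%02d", day))
      stop("malformed timestamp '", x, "': day out of range for month",
           call. = FALSE)
    secs[i] <- as.numeric(t)
    coarse[i] <- is.na(second)
  }
  instant(secs, coarse = coarse)
}

#' Construct an instant from seconds since epoch
#'
#' @param seconds numeric, whole seconds since the Unix epoch (UTC).
#' @param coarse logical, `TRUE` where only minute resolution is known.
#' @return an `instant` object.
#' @export
instant <- function(seconds, coarse = FALSE) {
  stopifnot(is.numeric(seconds), all(is.finite(seconds)))
  coarse <- rep_len(as.logical(coarse), length(seconds))
  structure(as.numeric(seconds), coarse = coarse, class = "instant")
}

#' @export
print.instant <- function(x, ...) {
  cat(format_timestamp(x), sep = "\n")
  invisible(x)
}

#' Is an instant coarse (minute resolution)?
#' @param x an `instant`.
#' @return logical vector.
#' @export
is_coarse <- function(x) {
  cf <- attr(x, "coarse")
  if (is.null(cf)) rep(FALSE, length(x)) else cf
}

#' Format an instant in the telemetry dialect
#'
#' Second-resolution instants render as `YYYY-MM-DD-HHMMSS`; coarse instants
#' as `YYYY-MM-DD-HHMM`, exactly the forms [parse_timestamp()] reads, so the
#' two functions round-trip.
#'
#' @param x an `instant` or numeric seconds since epoch.
#' @param coarse optional logical overriding the instant's own coarse flag.
#' @return character vector.
#' @export
format_timestamp <- function(x, coarse = NULL) {
  if (is.null(coarse)) coarse <- is_coarse(x)
  coarse <- rep_len(coarse, length(x))
  t <- as.POSIXct(as.numeric(x), origin = "1970-01-01", tz = "UTC")
  out <- character(length(x))
  out[!coarse] <- format(t[!coarse], "%Y-%m-%d-%H%M%S", tz = "UTC")
  out[coarse] <- format(t[coarse], "%Y-%m-%d-%H%M", tz = "UTC")
  out
}

#' Elapsed seconds between two instants
#'
#' Exact non-negative integer difference `b - a`. Both instants must be at
#' second resolution: coarse (minute-resolution) stamps cannot support exact
#' interval arithmetic and are rejected. An inverted pair signals corrupted
#' telemetry and raises an ordering error rather than returning a negative.
#'
#' @param a,b instants (or numeric seconds), `b >= a` elementwise.
#' @return integer seconds.
#' @examples
#' interval_seconds(parse_timestamp("2016-11-04-173424"),
#'                  parse_timestamp("2016-11-04-173427"))  # 3
#' @export
interval_seconds <- function(a, b) {
  if (any(is_coarse(a)) || any(is_coarse(b)))
    stop("interval_seconds requires second-resolution instants", call. = FALSE)
  a <- as.numeric(a); b <- as.numeric(b)
  if (any(b < a))
    stop("ordering error: second instant precedes first (b < a); ",
         "telemetry timestamps must be non-decreasing", call. = FALSE)
  as.integer(round(b - a))
}

#' Truncate an instant to minute resolution
#'
#' Emulates a receipt stamp from a device that only reports minutes: the
#' result is floored to the minute and flagged coarse.
#'
#' @param x an `instant` or numeric seconds.
#' @return a coarse `instant`.
#' @export
to_minute <- function(x) {
  instant(floor(as.numeric(x) / 60) * 60, coarse = TRUE)
}
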