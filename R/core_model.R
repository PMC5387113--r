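#' Domain model: patients, sensors, readings, rules, events
#'
#' Plain-list S3 records shared by every other module. Readings flow through
#' the system as data frames (one row per measurement); the constructors here
#' validate single records and document the field contracts.
#'
#' @name core_model
NULL

#' Sensor modalities and their fixed units
#' @keywords internal
MODALITIES <- c(heart_rate = "bpm",
                body_temperature = "C",
                spo2 = "%",
                accelerometer = "g",
                signal_quality_channel = "dimensionless")

SIGNAL_QUALITIES <- c("good", "poor", "missing")
ACTIVITIES <- c("rest", "active", "unknown")
CHANNELS <- c("sms", "email", "voice", "bluetooth", "console")
SEXES <- c("female", "male", "other", "unknown")

#' Patient profile
#'
#' A monitored patient with a unique id and an RFID bracelet tag used as the
#' identification code at the bedside.
#'
#' @param patient_id opaque unique string.
#' @param rfid_tag unique hex string (bracelet tag).
#' @param name display name.
#' @param age years, integer >= 0.
#' @param sex one of `"female"`, `"male"`, `"other"`, `"unknown"`.
#' @param location ward/room context key the patient currently occupies.
#' @return a `patient_profile` list.
#' @export
patient_profile <- function(patient_id, rfid_tag, name = patient_id,
                            age = NA_integer_, sex = "unknown",
                            location = "default") {
  stopifnot(is.character(patient_id), nzchar(patient_id),
            is.character(rfid_tag), nzchar(rfid_tag))
  if (!grepl("^[0-9A-Fa-f]+$", rfid_tag))
    stop("rfid_tag must be a hex string, got '", rfid_tag, "'", call. = FALSE)
  if (!is.na(age) && (age < 0 || age != round(age)))
    stop("age must be a non-negative integer", call. = FALSE)
  sex <- match.arg(sex, SEXES)
  structure(list(patient_id = patient_id, rfid_tag = toupper(rfid_tag),
                 name = name, age = as.integer(age), sex = sex,
                 location = location),
            class = "patient_profile")
}

#' Sensor specification
#'
#' @param sensor_id opaque string.
#' @param modality one of `heart_rate`, `body_temperature`, `spo2`,
#'   `accelerometer`, `signal_quality_channel`. The unit is fixed by the
#'   modality (bpm, C, %, g, dimensionless) and cannot be overridden.
#' @param sample_period seconds between samples, > 0.
#' @return a `sensor_spec` list.
#' @export
sensor_spec <- function(sensor_id, modality, sample_period = 1) {
  modality <- match.arg(modality, names(MODALITIES))
  stopifnot(is.numeric(sample_period), sample_period > 0)
  structure(list(sensor_id = sensor_id, modality = modality,
                 unit = unname(MODALITIES[modality]),
                 sample_period = sample_period),
            class = "sensor_spec")
}

#' One timestamped sensor measurement
#'
#' @param patient_id,sensor_id identifiers.
#' @param timestamp instant or numeric seconds (simulated clock, 1 s
#'   resolution).
#' @param value finite numeric in the sensor's unit.
#' @param signal_quality `"good"`, `"poor"` or `"missing"` — the sensor's own
#'   contact/quality self-report.
#' @param activity `"rest"`, `"active"` or `"unknown"` — accelerometer
#'   context at measurement time.
#' @return a one-row data frame in the canonical reading layout.
#' @export
reading <- function(patient_id, sensor_id, timestamp, value,
                    signal_quality = "good", activity = "rest") {
  signal_quality <- match.arg(signal_quality, SIGNAL_QUALITIES)
  activity <- match.arg(activity, ACTIVITIES)
  if (!is.finite(value)) stop("reading value must be finite", call. = FALSE)
  data.frame(patient_id = patient_id, sensor_id = sensor_id,
             timestamp = as.numeric(timestamp), value = as.numeric(value),
             signal_quality = signal_quality, activity = activity,
             stringsAsFactors = FALSE)
}

#' Validate a data frame of readings
#'
#' Checks the canonical column set, finite values, known quality/activity
#' levels, and (for stream input) per-(patient, sensor) monotone
#' non-decreasing timestamps. Stores validate with `ordered = FALSE`: they
#' accept batches in any order and sort on query.
#'
#' @param df a readings data frame.
#' @param ordered enforce per-stream timestamp monotonicity.
#' @return `df`, invisibly, if valid; otherwise an error.
#' @export
validate_readings <- function(df, ordered = TRUE) {
  required <- c("patient_id", "sensor_id", "timestamp", "value",
                "signal_quality", "activity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("readings missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) return(invisible(df))
  if (!all(is.finite(df$value)))
    stop("readings contain non-finite values", call. = FALSE)
  if (!all(df$signal_quality %in% SIGNAL_QUALITIES))
    stop("unknown signal_quality level in readings", call. = FALSE)
  if (!all(df$activity %in% ACTIVITIES))
    stop("unknown activity level in readings", call. = FALSE)
  if (ordered) {
    bad <- vapply(split(df$timestamp, paste(df$patient_id, df$sensor_id)),
                  function(ts) is.unsorted(ts), logical(1))
    if (any(bad))
      stop("timestamps not monotone non-decreasing for stream(s): ",
           paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Desired value range (DVR)
#'
#' The interval of values considered normal for a patient and sensor, e.g.
#' 36.0-36.6 C for body temperature. Bounds are inclusive: a value exactly at
#' a bound is normal; anomalies are strictly outside the range.
#'
#' @param low,high numeric bounds, `low <= high`.
#' @param modality sensor modality the range applies to.
#' @param patient_id patient key, or `"default"` for a modality default.
#' @param context context key (ward/room), `"default"` if unspecified.
#' @return a `dvr` list.
#' @export
dvr <- function(low, high, modality, patient_id = "default",
                context = "default") {
  stopifnot(is.numeric(low), is.numeric(high))
  if (low > high)
    stop("invalid DVR: low (", low, ") > high (", high, ")", call. = FALSE)
  modality <- match.arg(modality, names(MODALITIES))
  structure(list(low = as.numeric(low), high = as.numeric(high),
                 modality = modality, patient_id = patient_id,
                 context = context),
            class = "dvr")
}

#' Anomalous-value rule
#'
#' One side of the complement of a DVR, carrying the clinical label raised
#' when a value falls on that side (e.g. `below_low` of a 36.0-36.6 C range
#' is Hypothermia; `above_high` is Hyperthermia).
#'
#' @param side `"below_low"` or `"above_high"`.
#' @param label non-empty clinical anomaly label.
#' @return an `anomaly_rule` list.
#' @export
anomaly_rule <- function(side, label) {
  side <- match.arg(side, c("below_low", "above_high"))
  if (!is.character(label) || !nzchar(label))
    stop("anomaly label must be a non-empty string", call. = FALSE)
  structure(list(side = side, label = label), class = "anomaly_rule")
}

#' Anomaly event
#'
#' A reading judged anomalous, with its label and the retrieval (T1) and
#' detection (T2) timestamps of the monitoring workflow.
#'
#' @param reading one-row reading data frame.
#' @param label clinical anomaly label.
#' @param t1 instant the monitoring agent retrieved the batch containing the
#'   reading.
#' @param t2 instant the anomaly was detected; `t2 >= t1`.
#' @return an `anomaly_event` list.
#' @export
anomaly_event <- function(reading, label, t1, t2) {
  t1 <- as.numeric(t1); t2 <- as.numeric(t2)
  if (t2 < t1)
    stop("anomaly event with t2 < t1 (detection before retrieval)",
         call. = FALSE)
  structure(list(reading = reading, label = label, t1 = t1, t2 = t2),
            class = "anomaly_event")
}

#' Notification route
#'
#' Maps an anomaly label to the health provider responsible for it and the
#' channel used to reach them.
#'
#' @param label anomaly label.
#' @param provider_id health provider identifier.
#' @param channel one of `sms`, `email`, `voice`, `bluetooth`, `console`.
#' @param address channel-specific address (phone number, e-mail, ...).
#' @return a `notification_route` list.
#' @export
notification_route <- function(label, provider_id, channel, address = "") {
  channel <- match.arg(channel, CHANNELS)
  structure(list(label = label, provider_id = provider_id,
                 channel = channel, address = address),
            class = "notification_route")
}

#' Notification record
#'
#' The routing outcome of one anomaly through one route, carrying the
#' notification-side timestamps: T3 (routine start), T4 (message sent), and
#' T5 (message received, minute resolution).
#'
#' @param event an `anomaly_event`.
#' @param route a `notification_route`.
#' @param t3,t4 instants at second resolution, `t2 <= t3 <= t4`.
#' @param t5 coarse instant (minute resolution) of receipt, or `NA` if the
#'   channel produces no receipt.
#' @return a `notification_record` list.
#' @export
notification_record <- function(event, route, t3, t4, t5 = NA) {
  t3 <- as.numeric(t3); t4 <- as.numeric(t4)
  if (t3 < event$t2)
    stop("notification record with t3 < t2", call. = FALSE)
  if (t4 < t3)
    stop("notification record with t4 < t3", call. = FALSE)
  structure(list(event = event, route = route, t3 = t3, t4 = t4,
                 t5 = if (length(t5) == 1 && is.na(t5)) NA_real_
                      else as.numeric(t5)),
            class = "notification_record")
}

#' @export
print.patient_profile <- function(x, ...) {
  cat(sprintf("<patient %s '%s' tag=%s location=%s>\n",
              x$patient_id, x$name, x$rfid_tag, x$location))
  invisible(x)
}

#' @export
print.dvr <- function(x, ...) {
  cat(sprintf("<dvr %s [%g, %g] patient=%s context=%s>\n",
              x$modality, x$low, x$high, x$patient_id, x$context))
  invisible(x)
}
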