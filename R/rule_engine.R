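#' Rule engine: classification and false-alarm suppression
#'
#' A reading is classified against the effective DVR of its (patient,
#' modality, context): values inside the range (bounds inclusive) are normal;
#' values strictly below `low` or strictly above `high` raise the label of
#' the corresponding anomaly rule. Two false-alarm strategies run before
#' classification: the signal-quality gate suppresses readings whose sensor
#' self-reports unreliable contact, and activity-context adjustment widens
#' the heart-rate range while the patient is physically active so exertion
#' tachycardia does not trigger alerts.
#'
#' @name rule_engine
NULL

#' Default context-adjustment table
#'
#' Additive widening of the DVR high bound, per modality, applied while the
#' patient is active. The table is configuration, not code; the shipped
#' default widens heart rate by +40 bpm and leaves every other modality
#' untouched.
#'
#' @return named numeric vector (modality -> bpm/unit widening).
#' @export
default_context_table <- function() {
  c(heart_rate = 40)
}

#' Classify one reading against a DVR and its rules
#'
#' Trichotomy on finite values: exactly one of normal, the below-low label,
#' or the above-high label. Bounds are inclusive for normal, so a body
#' temperature of exactly 36.6 against the 36.0-36.6 range is normal, while
#' 37.8 is Hyperthermia.
#'
#' @param reading a one-row reading data frame (or list with a `value`).
#' @param dvr the effective `dvr`.
#' @param rules list with `below_low` and `above_high` [anomaly_rule()]s.
#' @return a `classification` list: `status` (`"normal"` or `"anomalous"`),
#'   `label` (only when anomalous), `rule_used`.
#' @export
classify <- function(reading, dvr, rules) {
  v <- as.numeric(reading$value)
  if (!is.finite(v)) stop("reading value must be finite", call. = FALSE)
  if (v < dvr$low) {
    classification("anomalous", rules$below_low$label, rules$below_low)
  } else if (v > dvr$high) {
    classification("anomalous", rules$above_high$label, rules$above_high)
  } else {
    classification("normal")
  }
}

classification <- function(status, label = NULL, rule_used = NULL) {
  structure(list(status = status, label = label, rule_used = rule_used),
            class = "classification")
}

#' Signal-quality gate
#'
#' When enabled, readings whose signal quality is not `"good"` are ignored
#' until the sensor reports a reliable value again: they are never
#' classified and never alerted, only logged as suppressed.
#'
#' @param reading a one-row reading data frame.
#' @param enabled logical; when `FALSE` every reading passes.
#' @return `"pass"` or `"suppress"`.
#' @export
quality_gate <- function(reading, enabled = TRUE) {
  if (enabled && reading$signal_quality != "good") "suppress" else "pass"
}

#' Activity-context range adjustment
#'
#' While the patient is active, the high bound of modalities listed in the
#' adjustment table is widened additively (default: heart rate +40 bpm);
#' other modalities, and the rest/unknown activity states, leave the DVR
#' unchanged.
#'
#' @param dvr a `dvr`.
#' @param activity `"rest"`, `"active"` or `"unknown"`.
#' @param table named numeric vector of per-modality widenings; see
#'   [default_context_table()].
#' @return the (possibly widened) `dvr`.
#' @export
context_adjust <- function(dvr, activity, table = default_context_table()) {
  if (length(table) && any(table < 0))
    stop("configuration error: context widening must be non-negative",
         call. = FALSE)
  if (!identical(activity, "active")) return(dvr)
  w <- table[dvr$modality]
  if (length(w) == 0 || is.na(w)) return(dvr)
  dvr$high <- dvr$high + unname(w)
  dvr
}

#' Classify a batch of readings
#'
#' Applies the full per-reading pipeline — quality gate, context adjustment,
#' DVR classification — to every row of a readings data frame, resolving the
#' effective rules per (patient, modality, context) from the knowledge base.
#' Suppressed readings are retained and marked, not dropped, so the log
#' supports auditing and oracle comparisons.
#'
#' @param readings data frame of readings.
#' @param kb a `knowledge_base`.
#' @param sensors named list mapping sensor_id -> [sensor_spec()] (supplies
#'   the modality per sensor).
#' @param quality_gate_enabled logical.
#' @param context_table see [context_adjust()].
#' @return `readings` with extra columns `status`
#'   (`normal` / `anomalous` / `suppressed_quality`) and `label` (`NA`
#'   unless anomalous).
#' @export
classify_stream <- function(readings, kb, sensors,
                            quality_gate_enabled = TRUE,
                            context_table = default_context_table()) {
  n <- nrow(readings)
  if (length(context_table) && any(context_table < 0))
    stop("configuration error: context widening must be non-negative",
         call. = FALSE)
  status <- rep("normal", n)
  label <- rep(NA_character_, n)
  if (n == 0) {
    readings$status <- character(0)
    readings$label <- character(0)
    return(readings)
  }
  modality <- vapply(readings$sensor_id, function(sid) {
    spec <- sensors[[sid]]
    if (is.null(spec)) stop("unknown sensor_id '", sid, "'", call. = FALSE)
    spec$modality
  }, character(1), USE.NAMES = FALSE)

  suppressed <- quality_gate_enabled & readings$signal_quality != "good"

  # resolve effective rules once per (patient, modality) group, then work
  # vectorised within the group
  grp <- paste(readings$patient_id, modality, sep = "|")
  for (g in unique(grp)) {
    idx <- which(grp == g & !suppressed)
    if (!length(idx)) next
    eff <- effective_rules(kb, readings$patient_id[idx[1]], modality[idx[1]])
    widen <- context_table[modality[idx[1]]]
    widen <- if (length(widen) == 0 || is.na(widen)) 0 else unname(widen)
    high <- eff$dvr$high + ifelse(readings$activity[idx] == "active",
                                  widen, 0)
    v <- readings$value[idx]
    below <- v < eff$dvr$low
    above <- v > high
    status[idx[below]] <- "anomalous"
    status[idx[above]] <- "anomalous"
    label[idx[below]] <- eff$rules$below_low$label
    label[idx[above]] <- eff$rules$above_high$label
  }
  status[suppressed] <- "suppressed_quality"
  readings$status <- status
  readings$label <- label
  readings
}

#' Reassign a patient to a new monitoring context
#'
#' A change of room or ward can invalidate the monitoring parameters defined
#' for a patient; reconfiguration points subsequent [effective_rules()]
#' resolutions at the new context. The update is atomic — the returned
#' knowledge base is a new value, so no reading is ever classified against a
#' half-updated configuration — and is recorded in the knowledge base's
#' reconfiguration log with the before/after contexts.
#'
#' @param kb a `knowledge_base`.
#' @param patient_id patient to move.
#' @param new_context target context key; must already be known to the
#'   knowledge base.
#' @return the updated `knowledge_base` (input is left untouched).
#' @export
reconfigure <- function(kb, patient_id, new_context) {
  if (!(new_context %in% kb$contexts))
    stop("unknown context '", new_context, "'; knowledge base unchanged",
         call. = FALSE)
  before <- patient_context(kb, patient_id)
  kb$assignments[patient_id] <- new_context
  entry <- data.frame(patient_id = patient_id, from = before,
                      to = new_context, stringsAsFactors = FALSE)
  log <- attr(kb, "reconfig_log")
  attr(kb, "reconfig_log") <- if (is.null(log)) entry else rbind(log, entry)
  kb
}

#' Reconfiguration audit log
#' @param kb a `knowledge_base`.
#' @return data frame with columns `patient_id`, `from`, `to` (zero rows if
#'   never reconfigured).
#' @export
reconfig_log <- function(kb) {
  log <- attr(kb, "reconfig_log")
  if (is.null(log))
    data.frame(patient_id = character(), from = character(),
               to = character(), stringsAsFactors = FALSE)
  else log
}
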