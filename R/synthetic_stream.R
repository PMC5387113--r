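#' Synthetic vital-sign streams with ground truth
#'
#' Stands in for the sensing hardware (microcontroller + pulse and
#' temperature sensors): a seeded, fully deterministic generator producing
#' per-modality baseline streams with injected anomalies, signal-quality
#' dropouts and activity episodes, together with a ground-truth track of
#' every injected anomaly. Baseline values are drawn from a Gaussian
#' truncated to the desired value range, so a baseline-only stream can never
#' raise an alert and the ground truth stays clean. Anomalies are injected
#' as explicit values (not offsets), so the expected label is forced by the
#' rule set.
#'
#' @name synthetic_stream
NULL

#' Default per-modality baselines
#'
#' Means sit mid-range of the shipped default DVRs (36.0-36.6 C body
#' temperature, 60-110 bpm heart rate) with mild physiological variation;
#' sample periods reflect a wearable reporting temperature more slowly than
#' pulse.
#'
#' @return named list of `list(mean, sd, sample_period)` per modality.
#' @export
default_baselines <- function() {
  list(body_temperature = list(mean = 36.3, sd = 0.12, sample_period = 2),
       heart_rate = list(mean = 80, sd = 8, sample_period = 1))
}

#' Describe a stream scenario
#'
#' @param seed integer RNG seed; the generated stream is a pure function of
#'   the scenario.
#' @param duration seconds of simulated recording, > 0.
#' @param baselines per-modality `list(mean, sd, sample_period)`; see
#'   [default_baselines()].
#' @param anomalies data frame with columns `time`, `modality`, `value`,
#'   `label` — each row injects `value` at the sample nearest `time` and
#'   records `label` as ground truth. Values must lie strictly outside the
#'   effective DVR (validated against the knowledge base at generation).
#' @param dropouts data frame with columns `start`, `end`, `quality`
#'   (`"poor"` or `"missing"`): signal quality over `[start, end)`.
#' @param activity data frame with columns `start`, `end`, `activity`:
#'   activity context over `[start, end)` (default rest elsewhere).
#' @param patient_id patient the stream belongs to.
#' @return a `stream_scenario` list.
#' @export
stream_scenario <- function(seed, duration,
                            baselines = default_baselines(),
                            anomalies = NULL, dropouts = NULL,
                            activity = NULL, patient_id = "p1") {
  stopifnot(is.numeric(seed), is.numeric(duration), duration > 0)
  empty_iv <- function(extra) {
    df <- data.frame(start = numeric(), end = numeric())
    df[[extra]] <- character()
    df
  }
  anomalies <- anomalies %||% data.frame(time = numeric(),
                                         modality = character(),
                                         value = numeric(),
                                         label = character(),
                                         stringsAsFactors = FALSE)
  dropouts <- dropouts %||% empty_iv("quality")
  activity <- activity %||% empty_iv("activity")
  for (iv in list(dropouts, activity)) {
    if (nrow(iv) && any(iv$start < 0 | iv$end > duration | iv$start > iv$end))
      stop("dropout/activity intervals must lie within [0, duration)",
           call. = FALSE)
  }
  if (nrow(anomalies) && any(anomalies$time < 0 |
                             anomalies$time >= duration))
    stop("anomaly times must lie within [0, duration)", call. = FALSE)
  structure(list(seed = as.integer(seed), duration = duration,
                 baselines = baselines, anomalies = anomalies,
                 dropouts = dropouts, activity = activity,
                 patient_id = patient_id),
            class = "stream_scenario")
}

# truncated-normal draws via inverse-CDF, exact within [lo, hi]
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(pmax(stats::qnorm(p, mean, sd), lo), hi)
}

#' Generate a reading stream and its ground-truth track
#'
#' Deterministic for a fixed scenario (the seed is part of the scenario).
#' Baselines are sampled on each modality's grid and truncated to the
#' effective DVR; injected anomalies replace the grid sample nearest their
#' scheduled time. Injection of a value inside the DVR is refused — it would
#' corrupt the ground truth.
#'
#' @param scenario a [stream_scenario()].
#' @param kb the `knowledge_base` the stream will be monitored against
#'   (supplies the DVRs for truncation and injection validation).
#' @return list with `readings` (canonical layout, timestamp-ordered),
#'   `truth` (data frame `time`, `modality`, `value`, `label`), `sensors`
#'   (named list of [sensor_spec()] used, one per modality).
#' @export
generate_stream <- function(scenario, kb) {
  stopifnot(inherits(scenario, "stream_scenario"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(scenario$seed)

  pid <- scenario$patient_id
  sensors <- list()
  parts <- list()
  truth <- data.frame(time = numeric(), modality = character(),
                      value = numeric(), label = character(),
                      stringsAsFactors = FALSE)

  for (modality in names(scenario$baselines)) {
    b <- scenario$baselines[[modality]]
    sid <- paste0(modality, "-1")
    sensors[[sid]] <- sensor_spec(sid, modality,
                                  sample_period = b$sample_period)
    eff <- effective_rules(kb, pid, modality)
    times <- seq(0, scenario$duration - 1e-9, by = b$sample_period)
    values <- rtrunc_norm(length(times), b$mean, b$sd,
                          eff$dvr$low, eff$dvr$high)

    inj <- scenario$anomalies[scenario$anomalies$modality == modality, ,
                              drop = FALSE]
    if (nrow(inj)) {
      slots <- integer(0)
      for (k in seq_len(nrow(inj))) {
        v <- inj$value[k]
        if (v >= eff$dvr$low && v <= eff$dvr$high)
          stop("scenario validation error: injected ", modality, " value ",
               v, " lies inside the DVR [", eff$dvr$low, ", ",
               eff$dvr$high, "] and would corrupt the ground truth",
               call. = FALSE)
        expect <- if (v < eff$dvr$low) eff$rules$below_low$label
                  else eff$rules$above_high$label
        if (!is.na(inj$label[k]) && inj$label[k] != expect)
          stop("scenario validation error: injected ", modality, " value ",
               v, " is labelled '", inj$label[k], "' but the rule set ",
               "assigns '", expect, "'", call. = FALSE)
        slot <- which.min(abs(times - inj$time[k]))
        if (slot %in% slots)
          stop("scenario validation error: two anomalies map to the same ",
               modality, " sample at t=", times[slot], call. = FALSE)
        slots <- c(slots, slot)
        values[slot] <- v
        truth <- rbind(truth,
                       data.frame(time = times[slot], modality = modality,
                                  value = v, label = expect,
                                  stringsAsFactors = FALSE))
      }
    }

    quality <- rep("good", length(times))
    for (k in seq_len(nrow(scenario$dropouts))) {
      d <- scenario$dropouts[k, ]
      quality[times >= d$start & times < d$end] <- d$quality
    }
    act <- rep("rest", length(times))
    for (k in seq_len(nrow(scenario$activity))) {
      a <- scenario$activity[k, ]
      act[times >= a$start & times < a$end] <- a$activity
    }

    parts[[modality]] <- data.frame(patient_id = pid, sensor_id = sid,
                                    timestamp = times, value = values,
                                    signal_quality = quality,
                                    activity = act,
                                    stringsAsFactors = FALSE)
  }

  readings <- do.call(rbind, parts)
  readings <- readings[order(readings$timestamp, readings$sensor_id), ]
  rownames(readings) <- NULL
  truth <- truth[order(truth$time, truth$modality), ]
  rownames(truth) <- NULL
  validate_readings(readings)
  list(readings = readings, truth = truth, sensors = sensors)
}

#' Compare detected anomalies against the ground-truth track
#'
#' Matches detections to truth rows on (modality, label) with a time
#' tolerance of one sample period. Unmatched truth rows are false
#' negatives; when a classification log is supplied, false negatives caused
#' by the quality gate and in-range-under-widening anomalies during activity
#' are tallied separately (a context-suppressed anomaly is working as
#' configured, not a detector miss).
#'
#' @param detected data frame of detections with columns `time`, `modality`,
#'   `label` (e.g. derived from [classify_stream()] anomalous rows or from
#'   anomaly events).
#' @param truth truth track from [generate_stream()].
#' @param sensors named list of [sensor_spec()] (per-modality sample
#'   periods → matching tolerance).
#' @param classified optional output of [classify_stream()] used to
#'   attribute false negatives.
#' @return list with counts `tp`, `fp`, `fn`, `fn_quality`,
#'   `context_suppressed`, and rates `precision`, `recall` (`NA` when
#'   undefined).
#' @export
ground_truth_compare <- function(detected, truth, sensors,
                                 classified = NULL) {
  tol_of <- function(modality) {
    for (s in sensors) if (s$modality == modality) return(s$sample_period)
    1
  }
  used <- logical(nrow(detected))
  tp <- 0L
  matched_truth <- logical(nrow(truth))
  # two passes: exact-time matches first, then within one sample period —
  # so a nearby detection never steals the slot of an exact one
  for (pass in c("exact", "tolerant")) {
    for (i in seq_len(nrow(truth))) {
      if (matched_truth[i]) next
      tol <- if (pass == "exact") 0 else tol_of(truth$modality[i])
      cand <- which(!used &
                      detected$modality == truth$modality[i] &
                      detected$label == truth$label[i] &
                      abs(detected$time - truth$time[i]) <= tol)
      if (length(cand)) {
        used[cand[1]] <- TRUE
        matched_truth[i] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  fp <- sum(!used)
  fn_rows <- truth[!matched_truth, , drop = FALSE]
  fn_quality <- 0L
  context_suppressed <- 0L
  if (!is.null(classified) && nrow(fn_rows)) {
    for (i in seq_len(nrow(fn_rows))) {
      hit <- classified[abs(classified$timestamp - fn_rows$time[i]) < 1e-9 &
                          abs(classified$value - fn_rows$value[i]) < 1e-9, ,
                        drop = FALSE]
      if (nrow(hit) == 0) next
      if (hit$status[1] == "suppressed_quality")
        fn_quality <- fn_quality + 1L
      else if (hit$status[1] == "normal" && hit$activity[1] == "active")
        context_suppressed <- context_suppressed + 1L
    }
  }
  fn <- nrow(fn_rows) - context_suppressed
  list(tp = tp, fp = fp, fn = fn,
       fn_quality = fn_quality, context_suppressed = context_suppressed,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' Write a scenario to YAML (or JSON)
#' @param scenario a [stream_scenario()].
#' @param path output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_scenario <- function(scenario, path) {
  obj <- unclass(scenario)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  else
    yaml::write_yaml(obj, path)
  invisible(path)
}

#' Load a scenario from YAML or JSON
#' @param path scenario file.
#' @return a [stream_scenario()].
#' @export
load_scenario <- function(path) {
  if (!file.exists(path))
    stop("scenario file not found: ", path, call. = FALSE)
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  # accept both row-form (list of records) and column-form (named list of
  # parallel vectors, as YAML serialises data frames)
  as_df <- function(x, cols) {
    if (is.null(x) || length(x) == 0) return(NULL)
    df <- if (is.data.frame(x)) {
      x
    } else if (!is.null(names(x)) && all(cols %in% c(names(x), "label"))) {
      if (length(x[[cols[1]]]) == 0) return(NULL)
      as.data.frame(lapply(x[intersect(cols, names(x))], unlist),
                    stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(x, function(r)
        as.data.frame(r[intersect(cols, names(r))],
                      stringsAsFactors = FALSE)))
    }
    if (nrow(df) == 0) return(NULL)
    if ("label" %in% cols && is.null(df$label)) df$label <- NA_character_
    df[, cols]
  }
  stream_scenario(seed = obj$seed, duration = obj$duration,
                  baselines = obj$baselines,
                  anomalies = as_df(obj$anomalies,
                                    c("time", "modality", "value", "label")),
                  dropouts = as_df(obj$dropouts,
                                   c("start", "end", "quality")),
                  activity = as_df(obj$activity,
                                   c("start", "end", "activity")),
                  patient_id = obj$patient_id %||% "p1")
}
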