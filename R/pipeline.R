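#' Monitoring pipeline: detection, notification, delay telemetry
#'
#' Wires the agents into the monitoring workflow. A monitoring agent with a
#' ticker behaviour retrieves new readings each cycle (stamping T1),
#' classifies them — quality gate, context adjustment, DVR rules — and
#' stamps T2 on each detected anomaly, sending one message per anomaly to
#' the notification agent. The notification agent's one-shot behaviour
#' stamps T3 when its routine starts, dispatches through the channel
#' adapter for each route of the label, stamps T4 on send and T5 (minute
#' resolution) on the adapter's receipt. Four latency metrics follow:
#' DAI = T2 - T1, NSI = T3 - T2, NP = T4 - T3, NRI = T5 - T4 (reported as a
#' bound pair because T5 is coarse).
#'
#' @name monitoring_pipeline
NULL

#' Channel adapter stub
#'
#' Stand-in for a real delivery channel (SMS gateway, e-mail, ...) with
#' configurable simulated latency and receipt delay. `fail_times` makes the
#' first sends fail, to exercise the retry policy.
#'
#' @param latency simulated seconds between routine start and message sent.
#' @param receipt_delay simulated seconds between send and receipt; the
#'   receipt stamp is truncated to minute resolution (handsets do not
#'   report sub-minute receipt times). `NA` for channels with no receipt.
#' @param fail_times number of initial send attempts that fail.
#' @return a `channel_adapter` (environment with a `send` function).
#' @export
channel_adapter <- function(latency = 0, receipt_delay = 0, fail_times = 0) {
  env <- new.env(parent = emptyenv())
  env$failures_left <- fail_times
  env$latency <- latency
  env$receipt_delay <- receipt_delay
  env$send <- function() {
    if (env$failures_left > 0) {
      env$failures_left <- env$failures_left - 1
      return(list(ok = FALSE))
    }
    list(ok = TRUE, latency = env$latency,
         receipt_delay = env$receipt_delay)
  }
  class(env) <- "channel_adapter"
  env
}

#' Default channel adapters
#'
#' Console: instantaneous, no delivery delay (T3 = T4). Simulated SMS: 2 s
#' send latency and a 30 s receipt delay, stamped at minute resolution.
#' Email/voice/bluetooth share the console stub by default.
#'
#' @return named list of [channel_adapter()]s keyed by channel.
#' @export
default_channels <- function() {
  list(console = channel_adapter(0, 0),
       sms = channel_adapter(2, 30),
       email = channel_adapter(0, 0),
       voice = channel_adapter(0, 0),
       bluetooth = channel_adapter(0, 0))
}

#' One monitoring cycle over the stored streams
#'
#' Retrieves readings not yet processed (per-stream high-water mark) with
#' timestamps up to the retrieval instant `t1`, runs each through the
#' quality gate, context adjustment and classification, and stamps T2 on
#' every anomaly. Each (patient, sensor) stream has its own analysis clock:
#' analysing one reading advances it by `analysis_seconds`, so the detection
#' delay of an anomaly is its position within its stream's retrieved batch
#' times the per-reading analysis cost. With `analysis_seconds` no larger
#' than the stream's sample period, every DAI is bounded by one ticker
#' period plus one sample period.
#'
#' @param store a reading store.
#' @param kb a `knowledge_base`.
#' @param sensors named list of [sensor_spec()] keyed by sensor_id.
#' @param state an environment holding `hwm` (named numeric, per-stream
#'   high-water marks) and accumulating `classified` rows; created by
#'   [run_simulation()] or by the caller.
#' @param t1 retrieval instant (simulated seconds).
#' @param analysis_seconds per-reading analysis cost in simulated seconds.
#' @param quality_gate_enabled,context_table see [classify_stream()].
#' @return list of [anomaly_event()]s detected this cycle.
#' @export
monitor_step <- function(store, kb, sensors, state, t1,
                         analysis_seconds = 1,
                         quality_gate_enabled = TRUE,
                         context_table = default_context_table()) {
  batch <- tryCatch(store$query(to = t1 + 1), error = function(e) NULL)
  if (is.null(batch)) return(list())  # store failure: skip, retry next tick
  if (is.null(state$hwm)) state$hwm <- numeric()
  key <- paste(batch$patient_id, batch$sensor_id)
  seen <- state$hwm[key]
  new <- is.na(seen) | batch$timestamp > seen
  batch <- batch[new, , drop = FALSE]
  if (nrow(batch) == 0) return(list())
  batch <- batch[order(batch$timestamp, batch$sensor_id), , drop = FALSE]

  cls <- classify_stream(batch, kb, sensors,
                         quality_gate_enabled = quality_gate_enabled,
                         context_table = context_table)
  cls$t1 <- t1
  # each stream is analysed by its own monitoring behaviour, so the
  # within-tick analysis clock advances per stream, not across streams
  stream <- paste(cls$patient_id, cls$sensor_id)
  cls$t2 <- t1 + stats::ave(seq_len(nrow(cls)), stream,
                            FUN = seq_along) * analysis_seconds
  state$classified <- if (is.null(state$classified)) cls
                      else rbind(state$classified, cls)
  for (i in seq_len(nrow(batch))) {
    k <- paste(batch$patient_id[i], batch$sensor_id[i])
    state$hwm[k] <- max(batch$timestamp[i], state$hwm[k], na.rm = TRUE)
  }

  hits <- which(cls$status == "anomalous")
  lapply(hits, function(i)
    anomaly_event(cls[i, names(empty_readings())], cls$label[i],
                  t1 = t1, t2 = cls$t2[i]))
}

#' Route and dispatch one anomaly
#'
#' Stamps T3 at routine start, fans the event out to every route configured
#' for its label (one record per (event, route)), dispatching through the
#' channel adapter with a bounded retry policy. Events whose label has no
#' route are parked in an explicit unrouted queue — a configuration gap must
#' be visible, never fatal.
#'
#' @param event an [anomaly_event()].
#' @param routes routing table (data frame as in a `knowledge_base`).
#' @param channels named list of [channel_adapter()]s.
#' @param t3 instant the notification routine starts.
#' @param retry_attempts maximum send attempts per route.
#' @param retry_delay simulated seconds between attempts.
#' @return list with `records` (list of [notification_record()]s, each with
#'   a `status` attribute `"sent"` or `"failed"`) and `unrouted` (the event,
#'   or `NULL`).
#' @export
notify <- function(event, routes, channels = default_channels(),
                   t3 = event$t2, retry_attempts = 3, retry_delay = 1) {
  my_routes <- routes[routes$label == event$label, , drop = FALSE]
  if (nrow(my_routes) == 0)
    return(list(records = list(), unrouted = event))
  records <- vector("list", nrow(my_routes))
  for (i in seq_len(nrow(my_routes))) {
    rt <- notification_route(my_routes$label[i], my_routes$provider_id[i],
                             my_routes$channel[i], my_routes$address[i])
    adapter <- channels[[rt$channel]]
    if (is.null(adapter))
      stop("no adapter configured for channel '", rt$channel, "'",
           call. = FALSE)
    t_attempt <- t3
    outcome <- NULL
    for (a in seq_len(retry_attempts)) {
      res <- adapter$send()
      if (res$ok) { outcome <- res; break }
      t_attempt <- t_attempt + retry_delay
    }
    if (is.null(outcome)) {
      rec <- notification_record(event, rt, t3 = t3, t4 = t_attempt)
      attr(rec, "status") <- "failed"
    } else {
      t4 <- t_attempt + outcome$latency
      t5 <- if (is.na(outcome$receipt_delay)) NA
            else as.numeric(to_minute(t4 + outcome$receipt_delay))
      rec <- notification_record(event, rt, t3 = t3, t4 = t4, t5 = t5)
      attr(rec, "status") <- "sent"
    }
    records[[i]] <- rec
  }
  list(records = records, unrouted = NULL)
}

#' Compute the delay report from notification records
#'
#' Per record: DAI = T2 - T1 (detection delay), NSI = T3 - T2 (handoff
#' delay), NP = T4 - T3 (notification routine duration), all exact integer
#' seconds. T5 is minute-resolution, so NRI is reported as a lower/upper
#' bound pair: the true receipt time lies anywhere within the stamped
#' minute. Aggregates are arithmetic means of the rows (2 decimals).
#'
#' @param records list of [notification_record()]s, or a data frame with
#'   numeric columns `t1`..`t5` (`t5` optional/`NA`, minute-floored).
#' @return a `delay_report`: list with `rows` (per-record data frame with
#'   `t1`..`t5`, `dai`, `nsi`, `np`, `nri_lower`, `nri_upper`) and
#'   `summary` (`mean_dai`, `mean_nsi`, `mean_np`, `n`).
#' @export
compute_delays <- function(records) {
  df <- if (is.data.frame(records)) records else {
    do.call(rbind, lapply(records, function(r)
      data.frame(t1 = r$event$t1, t2 = r$event$t2, t3 = r$t3, t4 = r$t4,
                 t5 = r$t5, label = r$event$label,
                 provider_id = r$route$provider_id,
                 channel = r$route$channel, stringsAsFactors = FALSE)))
  }
  if (is.null(df) || nrow(df) == 0) {
    return(structure(list(
      rows = data.frame(t1 = numeric(), t2 = numeric(), t3 = numeric(),
                        t4 = numeric(), t5 = numeric(), dai = integer(),
                        nsi = integer(), np = integer(),
                        nri_lower = numeric(), nri_upper = numeric()),
      summary = list(mean_dai = NA_real_, mean_nsi = NA_real_,
                     mean_np = NA_real_, n = 0L)),
      class = "delay_report"))
  }
  for (i in seq_len(nrow(df))) {
    ts <- unlist(df[i, c("t1", "t2", "t3", "t4")])
    if (any(diff(ts) < 0))
      stop("ordering error in record ", i,
           ": timestamps T1..T4 must be non-decreasing", call. = FALSE)
  }
  df$dai <- interval_seconds(df$t1, df$t2)
  df$nsi <- interval_seconds(df$t2, df$t3)
  df$np <- interval_seconds(df$t3, df$t4)
  has_t5 <- !is.na(df$t5)
  df$nri_lower <- ifelse(has_t5, pmax(0, df$t5 - df$t4), NA_real_)
  df$nri_upper <- ifelse(has_t5, df$t5 + 59 - df$t4, NA_real_)
  if (any(has_t5 & df$nri_upper < 0))
    stop("ordering error: receipt minute precedes send time", call. = FALSE)
  structure(list(rows = df,
                 summary = list(mean_dai = round(mean(df$dai), 2),
                                mean_nsi = round(mean(df$nsi), 2),
                                mean_np = round(mean(df$np), 2),
                                n = nrow(df))),
            class = "delay_report")
}

#' @export
print.delay_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<delay_report: %d notification%s | mean DAI %.2f s, NSI %.2f s, NP %.2f s>\n",
    s$n, if (s$n == 1) "" else "s",
    s$mean_dai, s$mean_nsi, s$mean_np))
  invisible(x)
}

#' Run the full monitoring simulation
#'
#' Generates (or takes) a reading stream, loads it into a store, registers
#' the monitoring agent (ticker) and notification agent (one-shot) on a
#' simulated clock, runs the discrete-event loop, and returns the
#' notification records, delay report, classification log and event log.
#' Fully deterministic for a fixed scenario and configuration.
#'
#' @param kb a `knowledge_base`.
#' @param scenario a [stream_scenario()]; alternatively supply `readings` +
#'   `sensors` + `duration` directly (timestamps relative to 0).
#' @param readings,sensors,duration explicit stream input (ignored when
#'   `scenario` is given).
#' @param ticker_period monitoring cycle period, simulated seconds.
#' @param analysis_seconds per-reading analysis cost within a cycle.
#' @param delivery_latency message-bus latency, simulated seconds
#'   (default 0: same-tick handoff from detection to notification).
#' @param quality_gate_enabled,context_table see [classify_stream()].
#' @param channels named list of [channel_adapter()]s.
#' @param retry_attempts,retry_delay channel retry policy.
#' @param origin telemetry instant of simulated time zero (timestamp string
#'   or numeric epoch seconds); all exported timestamps are absolute.
#' @return list with `records`, `report` (a `delay_report`), `events`,
#'   `classified`, `unrouted`, `event_log`, `dead_letters`, `truth`
#'   (ground-truth track shifted to absolute time, when a scenario was
#'   used), `sensors`, `origin`.
#' @export
run_simulation <- function(kb, scenario = NULL, readings = NULL,
                           sensors = NULL, duration = NULL,
                           ticker_period = 6, analysis_seconds = 1,
                           delivery_latency = 0,
                           quality_gate_enabled = TRUE,
                           context_table = default_context_table(),
                           channels = default_channels(),
                           retry_attempts = 3, retry_delay = 1,
                           origin = "2020-01-01-080000") {
  if (is.character(origin)) origin <- as.numeric(parse_timestamp(origin))
  truth <- NULL
  if (!is.null(scenario)) {
    gen <- generate_stream(scenario, kb)
    readings <- gen$readings
    sensors <- gen$sensors
    duration <- scenario$duration
    truth <- gen$truth
    truth$time <- truth$time + origin
  }
  stopifnot(!is.null(readings), !is.null(sensors), !is.null(duration))
  readings$timestamp <- readings$timestamp + origin

  store <- MemoryStore$new()
  if (nrow(readings)) store$append(readings)

  state <- new.env(parent = emptyenv())
  state$records <- list()
  state$events <- list()
  state$unrouted <- list()

  rt <- AgentRuntime$new(start_time = origin,
                         delivery_latency = delivery_latency)

  monitor_action <- function(runtime, agent_id, time, message) {
    events <- monitor_step(store, kb, sensors, state, t1 = time,
                           analysis_seconds = analysis_seconds,
                           quality_gate_enabled = quality_gate_enabled,
                           context_table = context_table)
    for (ev in events) {
      state$events <- c(state$events, list(ev))
      runtime$send(agent_id, "notifier", "inform", payload = ev,
                   at = ev$t2)
    }
  }
  notify_action <- function(runtime, agent_id, time, message) {
    out <- notify(message$payload, kb$routes, channels = channels,
                  t3 = time, retry_attempts = retry_attempts,
                  retry_delay = retry_delay)
    state$records <- c(state$records, out$records)
    if (!is.null(out$unrouted))
      state$unrouted <- c(state$unrouted, list(out$unrouted))
  }

  rt$register_agent("monitor",
                    list(behavior("ticker", monitor_action,
                                  period = ticker_period)))
  rt$register_agent("notifier",
                    list(behavior("one_shot", notify_action)))

  # enough cycles to retrieve the last sample plus drain in-flight analysis
  # and deliveries (assumes analysis_seconds <= the fastest sample period)
  slack <- (ceiling(ticker_period) + 2) * max(1, analysis_seconds) +
    delivery_latency + retry_attempts * retry_delay
  rt$run_until(origin + duration + 2 * ticker_period + slack)

  list(records = state$records,
       report = compute_delays(state$records),
       events = state$events,
       classified = state$classified,
       unrouted = state$unrouted,
       event_log = rt$event_log(),
       dead_letters = rt$dead_letters(),
       truth = truth, sensors = sensors, origin = origin)
}

#' Detected anomalies of a simulation as a comparison-ready data frame
#'
#' @param sim result of [run_simulation()].
#' @return data frame with `time` (reading timestamp), `modality`, `label`.
#' @export
sim_detections <- function(sim) {
  if (!length(sim$events))
    return(data.frame(time = numeric(), modality = character(),
                      label = character(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(sim$events, function(ev) {
    spec <- sim$sensors[[ev$reading$sensor_id]]
    data.frame(time = ev$reading$timestamp, modality = spec$modality,
               label = ev$label, stringsAsFactors = FALSE)
  }))
}

#' Write a delay report in the notifications CSV dialect
#'
#' Columns `T1,T2,T3,T4,T5,DAI,NSI,NP`; timestamps in the compact telemetry
#' dialect, T5 at minute resolution.
#'
#' @param report a `delay_report` from [compute_delays()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_delay_csv <- function(report, path) {
  rows <- report$rows
  out <- data.frame(
    T1 = format_timestamp(rows$t1, coarse = FALSE),
    T2 = format_timestamp(rows$t2, coarse = FALSE),
    T3 = format_timestamp(rows$t3, coarse = FALSE),
    T4 = format_timestamp(rows$t4, coarse = FALSE),
    T5 = ifelse(is.na(rows$t5), "",
                format_timestamp(rows$t5, coarse = TRUE)),
    DAI = rows$dai, NSI = rows$nsi, NP = rows$np,
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a notifications CSV in the telemetry dialect
#'
#' @param path CSV with header `T1,T2,T3,T4,T5,DAI,NSI,NP` (interval
#'   columns optional), timestamps in the compact dialect.
#' @return data frame with numeric `t1`..`t5` plus any pre-filled interval
#'   columns (`DAI`, `NSI`, `NP`).
#' @export
read_delay_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("T1", "T2", "T3", "T4")
  if (!all(need %in% names(df)))
    stop("notifications CSV must have columns T1,T2,T3,T4", call. = FALSE)
  n <- nrow(df)
  out <- data.frame(t1 = numeric(n), t2 = numeric(n), t3 = numeric(n),
                    t4 = numeric(n), t5 = rep(NA_real_, n))
  for (i in seq_len(n)) {
    for (col in need) {
      t <- tryCatch(parse_timestamp(df[[col]][i]), error = function(e)
        stop("line ", i + 1, ": ", conditionMessage(e), call. = FALSE))
      out[[tolower(col)]][i] <- as.numeric(t)
    }
    if ("T5" %in% names(df) && nzchar(df$T5[i]))
      out$t5[i] <- tryCatch(as.numeric(parse_timestamp(df$T5[i])),
                            error = function(e)
        stop("line ", i + 1, ": ", conditionMessage(e), call. = FALSE))
  }
  for (col in c("DAI", "NSI", "NP"))
    if (col %in% names(df)) out[[col]] <- as.numeric(df[[col]])
  out
}
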