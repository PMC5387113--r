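# Shared fixtures and independent oracles, all built in code.

# The canonical ward configuration: heart rate 60-110 bpm
# (Bradyarrhythmias / Tachyarrhythmias), body temperature 36.0-36.6 C
# (Hypothermia / Hyperthermia), every label routed to a console provider.
ward_kb <- function(extra_entries = list(), extra_routes = NULL,
                    unrouted = character(), contexts = character(),
                    assignments = character()) {
  entries <- c(list(
    kb_entry("default", "heart_rate", 60, 110,
             "Bradyarrhythmias", "Tachyarrhythmias"),
    kb_entry("default", "body_temperature", 36.0, 36.6,
             "Hypothermia", "Hyperthermia")),
    extra_entries)
  routes <- data.frame(
    label = c("Bradyarrhythmias", "Tachyarrhythmias",
              "Hypothermia", "Hyperthermia"),
    provider_id = c("cardio-1", "cardio-1", "nurse-1", "nurse-1"),
    channel = "console", address = "stdout",
    stringsAsFactors = FALSE)
  if (!is.null(extra_routes)) routes <- rbind(routes, extra_routes)
  knowledge_base(entries, routes, unrouted = unrouted,
                 contexts = contexts, assignments = assignments)
}

ward_sensors <- function() {
  list("heart_rate-1" = sensor_spec("heart_rate-1", "heart_rate",
                                    sample_period = 1),
       "body_temperature-1" = sensor_spec("body_temperature-1",
                                          "body_temperature",
                                          sample_period = 2))
}

# a random but always-valid knowledge base, for round-trip properties
random_kb <- function(n_entries = 5) {
  modalities <- c("heart_rate", "body_temperature", "spo2")
  entries <- list()
  labels <- character()
  keys <- character()
  for (i in seq_len(n_entries)) {
    repeat {
      pid <- sample(c("default", paste0("p", 1:4)), 1)
      modality <- sample(modalities, 1)
      ctx <- sample(c("default", "icu", "ward-a"), 1)
      if (!(paste(pid, modality, ctx) %in% keys)) break
    }
    keys <- c(keys, paste(pid, modality, ctx))
    lo <- round(runif(1, 30, 80), 1)
    hi <- lo + round(runif(1, 0.5, 60), 1)
    lab <- paste0(c("Low", "High"), modality, "-", i)
    labels <- c(labels, lab)
    entries[[i]] <- kb_entry(pid, modality, lo, hi, lab[1], lab[2],
                             context = ctx)
  }
  routed <- labels[runif(length(labels)) < 0.8]
  routes <- if (length(routed)) {
    data.frame(label = routed,
               provider_id = sample(paste0("prov-", 1:3), length(routed),
                                    replace = TRUE),
               channel = sample(c("console", "sms", "email"),
                                length(routed), replace = TRUE),
               address = "x", stringsAsFactors = FALSE)
  } else NULL
  routes <- routes[!duplicated(routes[c("label", "provider_id")]), ,
                   drop = FALSE]
  knowledge_base(entries,
                 if (is.null(routes)) NULL else routes,
                 unrouted = setdiff(labels, routed))
}

# independent row-by-row classification oracle: same contract as
# classify_stream, implemented as a plain loop over pre-extracted vectors
oracle_classify <- function(readings, kb, sensors, gate = TRUE,
                            widen_table = default_context_table()) {
  n <- nrow(readings)
  status <- character(n)
  label <- rep(NA_character_, n)
  sq <- readings$signal_quality
  act <- readings$activity
  val <- readings$value
  pid <- readings$patient_id
  sid <- readings$sensor_id
  for (i in seq_len(n)) {
    if (gate && sq[i] != "good") {
      status[i] <- "suppressed_quality"
      next
    }
    modality <- sensors[[sid[i]]]$modality
    eff <- effective_rules(kb, pid[i], modality)
    lo <- eff$dvr$low
    hi <- eff$dvr$high
    if (act[i] == "active" && modality %in% names(widen_table))
      hi <- hi + widen_table[[modality]]
    if (val[i] < lo) {
      status[i] <- "anomalous"; label[i] <- eff$rules$below_low$label
    } else if (val[i] > hi) {
      status[i] <- "anomalous"; label[i] <- eff$rules$above_high$label
    } else {
      status[i] <- "normal"
    }
  }
  cbind(readings, status = status, label = label, stringsAsFactors = FALSE)
}

# brute-force enumeration of ticker firing times with the documented
# tie-break (time, agent registration order, behavior index)
oracle_ticker_firings <- function(specs, t0, t_end) {
  # specs: data.frame(agent_order, behavior_index, period)
  rows <- list()
  for (i in seq_len(nrow(specs))) {
    times <- seq(t0, t_end, by = specs$period[i])
    rows[[i]] <- data.frame(time = times,
                            agent_order = specs$agent_order[i],
                            behavior_index = specs$behavior_index[i])
  }
  out <- do.call(rbind, rows)
  out[order(out$time, out$agent_order, out$behavior_index), ,
      drop = FALSE]
}

# a scenario with k routed heart-rate/temperature anomalies under perfect
# conditions (good quality, rest activity)
k_anomaly_scenario <- function(k, seed = 7) {
  if (k == 0)
    return(stream_scenario(seed = seed, duration = 60))
  times <- seq(2, by = 4, length.out = k)
  values <- rep(c(45, 130), length.out = k)
  labels <- rep(c("Bradyarrhythmias", "Tachyarrhythmias"), length.out = k)
  stream_scenario(
    seed = seed, duration = max(times) + 10,
    anomalies = data.frame(time = times, modality = "heart_rate",
                           value = values, label = labels,
                           stringsAsFactors = FALSE))
}

reference_delays_path <- function() {
  system.file("extdata", "reference_delays.csv", package = "vitalagents")
}

make_readings <- function(...) {
  do.call(rbind, list(...))
}
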