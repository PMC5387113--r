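temp_rules <- function() {
  eff <- effective_rules(ward_kb(), "p1", "body_temperature")
  eff
}

test_that("worked classification examples from the rule tables", {
  eff <- temp_rules()
  # 37.8 C against the 36.0-36.6 range
  cl <- classify(list(value = 37.8), eff$dvr, eff$rules)
  expect_equal(cl$status, "anomalous")
  expect_equal(cl$label, "Hyperthermia")

  hr <- effective_rules(ward_kb(), "p1", "heart_rate")
  expect_equal(classify(list(value = 55), hr$dvr, hr$rules)$label,
               "Bradyarrhythmias")
  expect_equal(classify(list(value = 120), hr$dvr, hr$rules)$label,
               "Tachyarrhythmias")
})

test_that("values exactly at a DVR bound are normal", {
  eff <- temp_rules()
  expect_equal(classify(list(value = 36.6), eff$dvr, eff$rules)$status,
               "normal")
  expect_equal(classify(list(value = 36.0), eff$dvr, eff$rules)$status,
               "normal")
  expect_equal(classify(list(value = 35.999), eff$dvr, eff$rules)$label,
               "Hypothermia")
})

test_that("classification is a trichotomy on finite values", {
  set.seed(41)
  for (i in 1:200) {
    lo <- runif(1, -50, 50)
    d <- dvr(lo, lo + runif(1, 0, 100), "heart_rate")
    rules <- list(below_low = anomaly_rule("below_low", "L"),
                  above_high = anomaly_rule("above_high", "H"))
    v <- runif(1, -100, 200)
    cl <- classify(list(value = v), d, rules)
    branch <- c(normal = cl$status == "normal",
                below = identical(cl$label, "L"),
                above = identical(cl$label, "H"))
    expect_equal(sum(branch), 1)
    expect_equal(unname(branch["normal"]), v >= d$low && v <= d$high)
  }
})

test_that("the quality gate suppresses non-good readings when enabled", {
  r_poor <- reading("p1", "heart_rate-1", 0, 80, signal_quality = "poor")
  r_good <- reading("p1", "heart_rate-1", 0, 80)
  expect_equal(quality_gate(r_poor), "suppress")
  expect_equal(quality_gate(r_good), "pass")
  expect_equal(quality_gate(r_poor, enabled = FALSE), "pass")
})

test_that("activity context widens only the configured modality", {
  d <- dvr(60, 110, "heart_rate")
  expect_equal(context_adjust(d, "rest")$high, 110)
  expect_equal(context_adjust(d, "unknown")$high, 110)
  expect_equal(context_adjust(d, "active")$high, 150)  # +40 bpm default
  expect_equal(context_adjust(d, "active", c(heart_rate = 25))$high, 135)

  dt <- dvr(36.0, 36.6, "body_temperature")
  expect_equal(context_adjust(dt, "active")$high, 36.6)
  expect_error(context_adjust(d, "active", c(heart_rate = -5)),
               "configuration error")
})

test_that("suppressed readings are retained and marked, never alerted", {
  kb <- ward_kb()
  sensors <- ward_sensors()
  rd <- make_readings(
    reading("p1", "heart_rate-1", 0, 130, signal_quality = "poor"),
    reading("p1", "heart_rate-1", 1, 131),
    reading("p1", "heart_rate-1", 2, 80, signal_quality = "missing"))
  cls <- classify_stream(rd, kb, sensors)
  expect_equal(cls$status,
               c("suppressed_quality", "anomalous", "suppressed_quality"))
  expect_equal(nrow(cls), 3)  # retained for audit
  # quality wins over anomaly: the 130 bpm poor reading raises nothing
  expect_true(is.na(cls$label[1]))
})

test_that("widening a DVR never increases anomalies on a fixed stream", {
  set.seed(42)
  sensors <- ward_sensors()
  values <- runif(300, 30, 180)
  rd <- data.frame(patient_id = "p1", sensor_id = "heart_rate-1",
                   timestamp = seq_along(values), value = values,
                   signal_quality = "good", activity = "rest",
                   stringsAsFactors = FALSE)
  count_anomalies <- function(lo, hi) {
    kb <- knowledge_base(list(kb_entry("default", "heart_rate", lo, hi,
                                       "L", "H")),
                         unrouted = c("L", "H"))
    sum(classify_stream(rd, kb, sensors)$status == "anomalous")
  }
  base <- count_anomalies(60, 110)
  for (i in 1:20) {
    widen_lo <- runif(1, 0, 30)
    widen_hi <- runif(1, 0, 30)
    expect_lte(count_anomalies(60 - widen_lo, 110 + widen_hi), base)
  }
})

test_that("classify_stream agrees with the row-by-row oracle", {
  set.seed(43)
  kb <- ward_kb(extra_entries = list(
    kb_entry("p2", "heart_rate", 50, 100, "Bradyarrhythmias",
             "Tachyarrhythmias")))
  sensors <- ward_sensors()
  for (rep in 1:10) {
    n <- sample(50:300, 1)
    rd <- data.frame(
      patient_id = sample(c("p1", "p2"), n, replace = TRUE),
      sensor_id = sample(names(sensors), n, replace = TRUE),
      timestamp = 0, value = runif(n, 20, 200),
      signal_quality = sample(c("good", "good", "good", "poor"), n,
                              replace = TRUE),
      activity = sample(c("rest", "active", "unknown"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    rd$timestamp <- ave(rep(1, n), paste(rd$patient_id, rd$sensor_id),
                        FUN = cumsum)
    got <- classify_stream(rd, kb, sensors)
    want <- oracle_classify(rd, kb, sensors)
    expect_equal(got$status, want$status)
    expect_equal(got$label, want$label)
  }
})

test_that("reconfiguration atomically moves a patient between contexts", {
  kb <- ward_kb(extra_entries = list(
    kb_entry("default", "body_temperature", 36.0, 36.4, "Hypothermia",
             "Hyperthermia", context = "icu")))

  kb2 <- reconfigure(kb, "p1", "icu")
  # the new knowledge base resolves against the stricter ICU range
  expect_equal(effective_rules(kb2, "p1", "body_temperature")$dvr$high, 36.4)
  # the original is untouched (no half-updated state is observable)
  expect_equal(effective_rules(kb, "p1", "body_temperature")$dvr$high, 36.6)
  log <- reconfig_log(kb2)
  expect_equal(log$from, "default")
  expect_equal(log$to, "icu")

  # idempotent move is a no-op but still logged
  kb3 <- reconfigure(kb2, "p1", "icu")
  expect_equal(effective_rules(kb3, "p1", "body_temperature")$dvr$high, 36.4)
  expect_equal(nrow(reconfig_log(kb3)), 2)

  # unknown context: error, knowledge base unchanged
  expect_error(reconfigure(kb, "p1", "basement"), "unknown context")
  expect_equal(patient_context(kb, "p1"), "default")
})
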