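test_that("a fixed seed reproduces the stream exactly", {
  kb <- ward_kb()
  sc <- k_anomaly_scenario(10, seed = 99)
  g1 <- generate_stream(sc, kb)
  g2 <- generate_stream(sc, kb)
  expect_identical(g1$readings, g2$readings)
  expect_identical(g1$truth, g2$truth)
})

test_that("an injected 37.8 C reading carries the Hyperthermia ground truth", {
  kb <- ward_kb()
  sc <- stream_scenario(
    seed = 5, duration = 60,
    anomalies = data.frame(time = 30, modality = "body_temperature",
                           value = 37.8, label = NA_character_,
                           stringsAsFactors = FALSE))
  g <- generate_stream(sc, kb)
  expect_equal(g$truth$label, "Hyperthermia")
  expect_equal(g$truth$value, 37.8)
  cls <- classify_stream(g$readings, kb, g$sensors)
  hits <- cls[cls$status == "anomalous", ]
  expect_equal(nrow(hits), 1)
  expect_equal(hits$label, "Hyperthermia")
})

test_that("a declared label that contradicts the rule set is refused", {
  kb <- ward_kb()
  sc <- stream_scenario(
    seed = 5, duration = 60,
    anomalies = data.frame(time = 30, modality = "body_temperature",
                           value = 37.8, label = "Hypothermia",
                           stringsAsFactors = FALSE))
  expect_error(generate_stream(sc, kb), "assigns 'Hyperthermia'")
})

test_that("injecting a value inside the DVR is a scenario error", {
  kb <- ward_kb()
  sc <- stream_scenario(
    seed = 5, duration = 60,
    anomalies = data.frame(time = 30, modality = "body_temperature",
                           value = 36.3, label = NA_character_,
                           stringsAsFactors = FALSE))
  expect_error(generate_stream(sc, kb), "inside the DVR")
})

test_that("a zero-anomaly scenario has empty truth and raises no alerts", {
  kb <- ward_kb()
  g <- generate_stream(stream_scenario(seed = 3, duration = 120), kb)
  expect_equal(nrow(g$truth), 0)
  cls <- classify_stream(g$readings, kb, g$sensors)
  expect_equal(sum(cls$status == "anomalous"), 0)
})

test_that("baseline-only streams are alert-free for any seed", {
  kb <- ward_kb()
  for (seed in 1:100) {
    g <- generate_stream(stream_scenario(seed = seed, duration = 20), kb)
    cls <- classify_stream(g$readings, kb, g$sensors)
    expect_equal(sum(cls$status == "anomalous"), 0,
                 info = paste("seed", seed))
  }
})

test_that("detection is exact on clean scenarios: recall and precision 100%", {
  kb <- ward_kb()
  sc <- k_anomaly_scenario(12, seed = 8)
  g <- generate_stream(sc, kb)
  cls <- classify_stream(g$readings, kb, g$sensors)
  det <- cls[cls$status == "anomalous", ]
  detected <- data.frame(
    time = det$timestamp,
    modality = vapply(det$sensor_id,
                      function(s) g$sensors[[s]]$modality, character(1)),
    label = det$label, stringsAsFactors = FALSE)
  cmp <- ground_truth_compare(detected, g$truth, g$sensors,
                              classified = cls)
  expect_equal(cmp$tp, 12)
  expect_equal(cmp$fp, 0)
  expect_equal(cmp$fn, 0)
  expect_equal(cmp$precision, 1)
  expect_equal(cmp$recall, 1)
})

test_that("confusion tallies on a hand-computed 10-reading scenario", {
  # Hand-built stream, classified by hand against the ward rules
  # (HR 60-110, +40 when active; gate on):
  #   t=0 hr 80  good rest    -> normal
  #   t=1 hr 130 good rest    -> anomalous Tachy   (truth row, TP)
  #   t=2 hr 45  poor rest    -> suppressed        (truth row, FN quality)
  #   t=3 hr 80  good rest    -> normal
  #   t=4 hr 130 good active  -> normal (<=150)    (truth row, context)
  #   t=5 hr 160 good active  -> anomalous Tachy   (truth row, TP)
  #   t=6 hr 80  good rest    -> normal
  #   t=7 hr 55  good rest    -> anomalous Brady   (truth row, TP)
  #   t=8 hr 80  missing rest -> suppressed        (no truth row)
  #   t=9 hr 80  good rest    -> normal
  kb <- ward_kb()
  sensors <- ward_sensors()
  rd <- data.frame(
    patient_id = "p1", sensor_id = "heart_rate-1", timestamp = 0:9,
    value = c(80, 130, 45, 80, 130, 160, 80, 55, 80, 80),
    signal_quality = c("good", "good", "poor", "good", "good", "good",
                       "good", "good", "missing", "good"),
    activity = c("rest", "rest", "rest", "rest", "active", "active",
                 "rest", "rest", "rest", "rest"),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    time = c(1, 2, 4, 5, 7), modality = "heart_rate",
    value = c(130, 45, 130, 160, 55),
    label = c("Tachyarrhythmias", "Bradyarrhythmias", "Tachyarrhythmias",
              "Tachyarrhythmias", "Bradyarrhythmias"),
    stringsAsFactors = FALSE)
  cls <- classify_stream(rd, kb, sensors)
  det <- cls[cls$status == "anomalous", ]
  detected <- data.frame(time = det$timestamp, modality = "heart_rate",
                         label = det$label, stringsAsFactors = FALSE)
  cmp <- ground_truth_compare(detected, truth, sensors, classified = cls)
  expect_equal(cmp$tp, 3)
  expect_equal(cmp$fp, 0)
  expect_equal(cmp$fn, 1)                  # the quality-suppressed one
  expect_equal(cmp$fn_quality, 1)
  expect_equal(cmp$context_suppressed, 1)  # in widened range while active
})

test_that("scenarios round-trip through YAML and JSON files", {
  sc <- k_anomaly_scenario(3, seed = 21)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    save_scenario(sc, path)
    back <- load_scenario(path)
    expect_equal(back$seed, sc$seed)
    expect_equal(back$duration, sc$duration)
    expect_equal(back$anomalies$value, sc$anomalies$value)
    expect_equal(back$baselines, sc$baselines, tolerance = 1e-12)
  }
})
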