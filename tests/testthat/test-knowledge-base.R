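write_kb_xml <- function(text) {
  path <- withr::local_tempfile(fileext = ".xml",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}

test_that("an XML knowledge base with the temperature rules loads", {
  path <- write_kb_xml('
<knowledgeBase version="1">
  <patients>
    <patient id="default">
      <sensor modality="body_temperature" unit="C">
        <dvr low="36.0" high="36.6"/>
        <anomaly side="below_low" label="Hypothermia"/>
        <anomaly side="above_high" label="Hyperthermia"/>
      </sensor>
    </patient>
  </patients>
  <routes>
    <route label="Hypothermia" provider="n1" channel="console"/>
    <route label="Hyperthermia" provider="n1" channel="console"/>
  </routes>
</knowledgeBase>')
  kb <- load_knowledge_base(path)
  expect_length(kb$entries, 1)
  eff <- effective_rules(kb, "anyone", "body_temperature")
  expect_equal(eff$dvr$low, 36.0)
  expect_equal(eff$dvr$high, 36.6)
  expect_equal(eff$rules$below_low$label, "Hypothermia")
  expect_equal(eff$rules$above_high$label, "Hyperthermia")
})

test_that("heart-rate rules carry the arrhythmia labels", {
  kb <- ward_kb()
  eff <- effective_rules(kb, "p1", "heart_rate")
  expect_equal(eff$dvr$low, 60)
  expect_equal(eff$dvr$high, 110)
  expect_equal(eff$rules$below_low$label, "Bradyarrhythmias")
  expect_equal(eff$rules$above_high$label, "Tachyarrhythmias")
})

test_that("an empty patients document is an empty knowledge base", {
  path <- write_kb_xml(
    "<knowledgeBase><patients/><routes/></knowledgeBase>")
  kb <- load_knowledge_base(path)
  expect_length(kb$entries, 0)
  expect_equal(nrow(kb$routes), 0)
})

test_that("validation collects every violation, not just the first", {
  path <- write_kb_xml('
<knowledgeBase>
  <patients>
    <patient id="p1">
      <sensor modality="body_temperature">
        <dvr low="37.0" high="36.0"/>
        <anomaly side="below_low" label="A"/>
        <anomaly side="above_high" label="B"/>
      </sensor>
      <sensor modality="heart_rate">
        <dvr low="60" high="110"/>
        <anomaly side="below_low" label="Same"/>
        <anomaly side="above_high" label="Same"/>
      </sensor>
      <sensor modality="not_a_modality">
        <dvr low="0" high="1"/>
      </sensor>
    </patient>
  </patients>
  <routes/>
</knowledgeBase>')
  err <- tryCatch(load_knowledge_base(path), error = identity)
  expect_s3_class(err, "error")
  msg <- conditionMessage(err)
  expect_match(msg, "low > high")
  expect_match(msg, "distinct")
  expect_match(msg, "unknown modality")
})

test_that("duplicate (patient, modality, context) keys are a conflict", {
  path <- write_kb_xml('
<knowledgeBase>
  <patients>
    <patient id="p1">
      <sensor modality="heart_rate">
        <dvr low="60" high="110"/>
        <anomaly side="below_low" label="A"/>
        <anomaly side="above_high" label="B"/>
      </sensor>
      <sensor modality="heart_rate">
        <dvr low="50" high="120"/>
        <anomaly side="below_low" label="A"/>
        <anomaly side="above_high" label="B"/>
      </sensor>
    </patient>
  </patients>
  <routes>
    <route label="A" provider="x" channel="console"/>
    <route label="B" provider="x" channel="console"/>
  </routes>
</knowledgeBase>')
  expect_error(load_knowledge_base(path), "conflict")
})

test_that("a label neither routed nor marked unrouted fails validation", {
  expect_error(
    knowledge_base(list(kb_entry("default", "heart_rate", 60, 110,
                                 "Lost", "AlsoLost"))),
    "no notification route")
  # the same configuration is fine with an explicit unrouted marker
  kb <- knowledge_base(list(kb_entry("default", "heart_rate", 60, 110,
                                     "Lost", "AlsoLost")),
                       unrouted = c("Lost", "AlsoLost"))
  expect_length(kb$entries, 1)
})

test_that("save/load round trip is the identity", {
  kb <- ward_kb(contexts = "icu",
                assignments = c(p2 = "icu"))
  path <- withr::local_tempfile(fileext = ".xml")
  save_knowledge_base(kb, path)
  expect_true(kb_equal(load_knowledge_base(path), kb))
})

test_that("round trip holds across many generated knowledge bases", {
  set.seed(31)
  path <- withr::local_tempfile(fileext = ".xml")
  for (i in 1:30) {
    kb <- random_kb(n_entries = sample(1:8, 1))
    save_knowledge_base(kb, path)
    expect_true(kb_equal(load_knowledge_base(path), kb),
                info = paste("generated kb", i))
  }
})

test_that("saving refuses a knowledge base with an unmarked unrouted label", {
  kb <- ward_kb()
  kb$routes <- kb$routes[kb$routes$label != "Hypothermia", ]
  path <- withr::local_tempfile(fileext = ".xml")
  expect_error(save_knowledge_base(kb, path), "Hypothermia")
})

test_that("effective rules resolve most specific entry first", {
  kb <- ward_kb(
    extra_entries = list(
      kb_entry("p1", "body_temperature", 36.0, 37.0, "Hypothermia",
               "Hyperthermia"),
      kb_entry("p1", "body_temperature", 35.5, 36.9, "Hypothermia",
               "Hyperthermia", context = "icu"),
      kb_entry("default", "body_temperature", 35.8, 36.8, "Hypothermia",
               "Hyperthermia", context = "icu")))

  # patient+context beats everything
  expect_equal(effective_rules(kb, "p1", "body_temperature",
                               context = "icu")$dvr$low, 35.5)
  # patient default beats modality default
  expect_equal(effective_rules(kb, "p1", "body_temperature")$dvr$high, 37.0)
  # default+context beats plain default
  expect_equal(effective_rules(kb, "p9", "body_temperature",
                               context = "icu")$dvr$low, 35.8)
  # plain default as the last resort
  expect_equal(effective_rules(kb, "p9", "body_temperature")$dvr$high, 36.6)
})

test_that("a patient without an override gets the 36.0-36.6 default", {
  kb <- ward_kb()
  eff <- effective_rules(kb, "p7", "body_temperature")
  expect_equal(c(eff$dvr$low, eff$dvr$high), c(36.0, 36.6))
})

test_that("a modality with no entry at any level is a configuration error", {
  kb <- ward_kb()
  expect_error(effective_rules(kb, "p1", "spo2"), "configuration missing")
})

test_that("the JSON mirror of the knowledge base loads equivalently", {
  kb <- ward_kb()
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    version = "1",
    entries = lapply(unname(kb$entries), function(e)
      list(patient_id = e$patient_id, modality = e$modality,
           low = e$dvr$low, high = e$dvr$high,
           below_label = e$rules$below_low$label,
           above_label = e$rules$above_high$label,
           context = e$context)),
    routes = lapply(seq_len(nrow(kb$routes)), function(i)
      as.list(kb$routes[i, ]))), path, auto_unbox = TRUE)
  expect_true(kb_equal(load_knowledge_base(path), kb))
})
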