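Package: vitalagents
Title: Multi-Agent Simulation of Remote Patient Vital-Sign Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained, deterministic simulator and library for
    rule-based remote patient monitoring. Vital-sign readings (heart rate,
    body temperature) are classified against per-patient desired value
    ranges coded in an XML knowledge base; anomalies carry clinical labels
    (Hypothermia, Hyperthermia, Bradyarrhythmias, Tachyarrhythmias) and are
    routed to health-care providers through pluggable notification
    channels. Autonomous monitoring and notification agents with cyclic
    (ticker) and on-demand (one-shot) behaviours run on a simulated
    discrete-event clock, and the workflow records the T1-T5 timestamps
    from which detection and notification latency metrics (DAI, NSI, NP,
    NRI) are computed. Includes false-alarm suppression via signal-quality
    gating and activity-context range widening, pluggable reading stores,
    a seeded synthetic stream generator with ground-truth tracks, and
    command-line entry points for validation, simulation and delay
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    R6,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
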