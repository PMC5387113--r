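---
title: "Simulating rule-based remote patient monitoring with vitalagents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating rule-based remote patient monitoring with vitalagents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitalagents)
```

## The monitoring model

`vitalagents` models the classical threshold-based remote-monitoring
loop. A patient wears sensors that emit timestamped readings; a
*monitoring agent* polls the reading store cyclically, classifies each new
reading against the patient's configured normal ranges, and hands every
anomaly to a *notification agent* that routes it to the responsible health
provider over a messaging channel. The package's contribution is to make
this whole loop a deterministic, inspectable simulation: every latency in
the system is a pure function of the configuration, so alerting policies
can be compared exactly.

### Rules

The unit of configuration is the *desired value range* (DVR): an interval
`[low, high]` of values considered normal for one (patient, modality,
context) triple — for example 36.0–36.6 °C body temperature, or 60–110 bpm
heart rate. Each DVR carries exactly two anomaly rules covering the
complement of the range, each with a clinical label (Hypothermia /
Hyperthermia, Bradyarrhythmias / Tachyarrhythmias). Classification is a
trichotomy: every finite value is exactly one of normal, below-range or
above-range.

**Bounds are inclusive.** A value exactly at a bound is normal; anomalies
are strict inequalities (`v < low` or `v > high`). Clinical range
notation ("36.0–36.6 is normal, values above 36.6 are anomalous") reads
most naturally this way, and an exact tie should not wake a cardiologist.
This was a genuine design choice — the convention matters for values
sitting exactly on a bound, which truncated-noise baselines can produce.

**Resolution order.** Ranges compose from patient-specific entries and
modality defaults, each optionally per context (ward/room). Lookup is
deterministic, most specific first:
(patient, context) → (patient) → (default, context) → (default).
Moving a patient between contexts (`reconfigure()`) is atomic by
construction: the knowledge base is an immutable value, so a batch of
readings is always classified against exactly one configuration state,
and every move is recorded in an audit log.

### False-alarm suppression

Two pre-classification filters model the standard strategies against
false alarms:

* **Signal-quality gate** — readings whose sensor self-reports anything
  other than `good` contact are suppressed: never classified, never
  alerted, but retained and marked in the classification log for audit.
  When both suppression and an anomaly would apply, suppression wins; an
  unreliable 130 bpm reading is noise, not tachycardia.
* **Activity-context adjustment** — while the accelerometer reports
  `active`, the high bound of configured modalities is widened additively
  (shipped default: heart rate +40 bpm, other modalities untouched). We
  chose DVR widening over a detection grace period because it composes
  cleanly with the trichotomy and is monotone: widening a range can never
  create an anomaly. The widening amount is configuration, not code; +40
  bpm reflects the rough magnitude of exertion tachycardia in adults and
  is deliberately conservative.

### Agents and the simulated clock

The scheduler is a single-threaded discrete-event loop with two behaviour
kinds, mirroring the cyclic/on-demand split common in agent middleware:
*ticker* behaviours fire every `p` seconds, *one-shot* behaviours fire
once per delivered message. Concurrency is modelled, not real; the
contract is a total, documented event order:

* a ticker registered at `t0` fires at `t0, t0+p, …` — so a run to
  `t_end` fires exactly `⌊(t_end − t0)/p⌋ + 1` times. Firing at
  registration (rather than one period later) is a convention, flippable
  with `first_tick_after_period`; it makes the firing-count law clean and
  the first monitoring pass immediate.
* simultaneous events order by (agent registration order, behaviour
  index, scheduling sequence) — an arbitrary but fixed tie-break chosen
  purely for reproducibility;
* messages between a sender–receiver pair are delivered exactly once, in
  send order, after a configurable latency (default 0 s: same-tick
  handoff); unknown receivers dead-letter rather than crash or silently
  drop.

Identical configurations therefore produce byte-identical event logs,
which the test suite asserts literally.

### Timestamps and latency metrics

The workflow stamps five instants: T1 when the monitoring agent retrieves
a batch, T2 when an anomaly is detected, T3 when the notification routine
starts, T4 when the message is sent, T5 when it is received. Four
latency metrics follow: DAI = T2−T1, NSI = T3−T2, NP = T4−T3,
NRI = T5−T4.

Two modelling choices deserve explanation:

* **DAI as within-tick analysis latency.** T1 is stamped once per
  monitoring cycle; each (patient, sensor) stream then has its own
  analysis clock that advances by `analysis_seconds` (default 1 s) per
  reading examined, and T2 is stamped when the anomalous reading is
  reached. DAI is thus the anomaly's position in its stream's retrieved
  batch times the per-reading cost. Streams are analysed independently —
  each has its own monitoring behaviour — so whenever
  `analysis_seconds` ≤ the stream's sample period, every DAI is bounded
  by one ticker period plus one sample period, as is the total
  measurement-to-detection delay. The default of 1 s per reading
  produces DAI values of a few seconds at the default 6 s ticker, the
  regime a polling monitor over a slow store actually exhibits.
* **T5 is coarse.** Receipt stamps come from handsets that report minute
  resolution only, so T5 is floored to the minute and flagged; NRI is
  reported as a `[lower, upper]` bound pair (the true receipt lies
  anywhere in the stamped minute) instead of a fake exact value.
  Interval arithmetic on coarse stamps is refused rather than rounded.

Telemetry uses a compact timestamp dialect, `YYYY-MM-DD-HHMMSS` (and
`YYYY-MM-DD-HHMM` for coarse stamps), with ISO-8601 accepted on input.
There are no time zones and no sub-second resolution by design: the
simulated clock is integer seconds, UTC throughout.

## Tunable parameters

| parameter | unit | default | why |
|---|---|---|---|
| `ticker_period` | s | 6 | short polling cycle; readings wait at most one cycle |
| `analysis_seconds` | s/reading | 1 | per-reading analysis cost; keep ≤ sample period for the DAI bound |
| `delivery_latency` | s | 0 | same-tick handoff ⇒ NSI ≡ 0 |
| context widening | bpm | +40 (heart rate) | exertion tachycardia headroom; configuration, not code |
| console channel | s | 0 latency, 0 receipt | instantaneous local sink (T3 = T4) |
| simulated SMS | s | 2 latency, 30 receipt | gateway round-trip; receipt stamped at minute resolution |
| `retry_attempts` / `retry_delay` | –, s | 3, 1 | bounded channel retry before a failure record |
| quality gate | flag | on | suppress non-`good` readings |

## The synthetic stream generator

The generator (`stream_scenario()` / `generate_stream()`) stands in for
sensing hardware. Per modality it samples a regular grid
(defaults: heart rate every 1 s, temperature every 2 s) from a Gaussian
**truncated to the effective DVR** — baselines are mid-range
(36.3 ± 0.12 °C, 80 ± 8 bpm) with mild physiological variation. Anomalies
are injected as explicit values replacing the grid sample nearest their
scheduled time; injection refuses values inside the DVR (they would
corrupt the ground truth) and refuses declared labels that contradict the
rule set. Dropout and activity episodes overwrite the quality/activity
flags over half-open intervals. Everything is a pure function of the
scenario, whose seed is part of its definition.

Truncation is the key choice: it guarantees that baseline-only streams
can never alert, so every detection traces to an injected anomaly and
recall/precision against the ground-truth track are exact (100% on clean
scenarios), not statistical. The corresponding limitation is honesty
about what passing tests show: real vital signs have trends, circadian
structure, autocorrelation, artefacts that straddle thresholds, and
values that genuinely hover at range bounds. The generator demonstrates
that the *pipeline* is sound — conservation, ordering, latency laws — not
that threshold rules are clinically sufficient; detector performance on
real data is a property of the configured thresholds, which this package
treats as input.

Ground-truth matching (`ground_truth_compare()`) pairs detections with
truth rows by (modality, label) within one sample period, preferring
exact-time matches so a neighbouring detection never steals an exact
one's slot; false negatives are attributed to quality suppression or
activity-context widening when the classification log shows that cause,
since a suppressed alarm is the configuration working as intended, not a
detector miss.

## Storage and identification

Storage is a plugin surface (the framework-style *hot spot*): monitoring
code sees only the store contract — append, query over half-open
`[from, to)` ranges ordered by timestamp, per-stream high-water mark,
idempotent appends keyed on (patient, sensor, timestamp, value). Shipped
back-ends: in-memory, durable JSON-lines, and a buffering wrapper
implementing a cached-storage strategy (appends while the back-end is
down are buffered and flushed on recovery). The conformance suite asserts
the memory and JSON-lines back-ends observationally equivalent under the
same operation sequence, which is what makes the plugin claim testable.
Half-open ranges were chosen once for the whole package (queries, episode
intervals) to avoid double-counting boundary readings. Patients are
identified by unique RFID bracelet tags resolved against a registry;
unknown tags quarantine the reading, duplicate tags fail at load.

## Numerical and degenerate-input choices

* All clocks are integer seconds; interval arithmetic is exact integer
  subtraction with an ordering check (inverted pairs signal corrupted
  telemetry and raise, never return negatives).
* Knowledge-base validation is eager and exhaustive: every violation is
  collected and reported at once, so configuration mistakes surface
  before monitoring starts, not one-by-one.
* Unrouted anomaly labels must be declared as such; an undeclared gap is
  a validation error, a declared one parks events in an explicit queue at
  run time. A monitoring system must not crash on a configuration gap —
  and must not hide it either.
* Truncated-normal sampling uses the inverse-CDF construction
  (`qnorm(runif(p_lo, p_hi))`), exact within the range, with a final
  clamp guarding floating-point edge cases at the bounds.
* Empty cases are first-class: empty knowledge bases, zero-anomaly
  scenarios, empty notification CSVs (header only) all round-trip.

## Problem sizes in the test suite

The suite exercises the oracle-equivalence property on 100 generated
scenarios (two of one hour / ~5,400 readings, the rest 40–400 s),
conservation at k ∈ {0, 1, 10, 100} injected anomalies, the latency bound
over 50 seeded runs, the scheduler law over randomized periods and
horizons, and 100 seeds of baseline-only false-alarm checks — sizes
chosen so the full suite completes in well under a minute while covering
every contract. The acceptance script re-derives the headline quantities
at the same sizes.

## Known limitations

* Threshold rules only: no trend, multivariate or learned detection.
* Channels are simulated adapters; no real SMS/e-mail/voice delivery, no
  provider acknowledgment workflows or escalation.
* Single-node, single-threaded simulation; distribution and true
  concurrency are out of scope, as are time zones and sub-second timing.
* NRI is inherently a bound, not a point estimate, as long as receipt
  stamps are minute-coarse.
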