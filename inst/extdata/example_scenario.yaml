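# A short monitored episode: 5 minutes of temperature + pulse with three
# injected anomalies (one hyperthermia, one brady-, one tachyarrhythmia).
seed: 42
duration: 300
patient_id: p1
baselines:
  body_temperature:
    mean: 36.3
    sd: 0.12
    sample_period: 2
  heart_rate:
    mean: 80.0
    sd: 8.0
    sample_period: 1
anomalies:
  - time: 60
    modality: body_temperature
    value: 37.8
    label: Hyperthermia
  - time: 150
    modality: heart_rate
    value: 48.0
    label: Bradyarrhythmias
  - time: 240
    modality: heart_rate
    value: 131.0
    label: Tachyarrhythmias
dropouts: []
activity: []
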