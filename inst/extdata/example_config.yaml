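knowledge_base: default_kb.xml
scenario: example_scenario.yaml
ticker_period: 6
analysis_seconds: 1
delivery_latency: 0
quality_gate: true
origin: "2020-01-01-080000"
out_dir: vitalagents-out
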