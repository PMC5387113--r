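<?xml version="1.0" encoding="UTF-8"?>
<knowledgeBase version="1" author="ward-admin">
  <contexts>
    <context name="icu"/>
  </contexts>
  <patients>
    <patient id="default">
      <sensor modality="heart_rate" unit="bpm" context="default">
        <dvr low="60" high="110"/>
        <anomaly side="below_low" label="Bradyarrhythmias"/>
        <anomaly side="above_high" label="Tachyarrhythmias"/>
      </sensor>
      <sensor modality="body_temperature" unit="C" context="default">
        <dvr low="36.0" high="36.6"/>
        <anomaly side="below_low" label="Hypothermia"/>
        <anomaly side="above_high" label="Hyperthermia"/>
      </sensor>
    </patient>
  </patients>
  <routes>
    <route label="Bradyarrhythmias" provider="cardio-1" channel="console" address="stdout"/>
    <route label="Tachyarrhythmias" provider="cardio-1" channel="console" address="stdout"/>
    <route label="Hypothermia" provider="nurse-1" channel="console" address="stdout"/>
    <route label="Hyperthermia" provider="nurse-1" channel="console" address="stdout"/>
  </routes>
</knowledgeBase>
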