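patient_id,rfid_tag,name,age,sex,location
p1,A1B2C3D4,Alex Doe,67,unknown,default
p2,0F0E0D0C,Sam Roe,54,unknown,icu
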