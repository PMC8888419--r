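site_id,sand_risk,temp_risk
P01,HIGH,HIGH
P02,HIGH,HIGH
P03,HIGH,HIGH
P04,HIGH,HIGH
P05,HIGH,HIGH
P06,HIGH,HIGH
P07,HIGH,HIGH
P08,HIGH,HIGH
P09,HIGH,HIGH
P10,HIGH,HIGH
P11,HIGH,LOW
P12,HIGH,LOW
P13,HIGH,LOW
P14,HIGH,LOW
P15,HIGH,LOW
P16,HIGH,LOW
P17,HIGH,LOW
P18,HIGH,LOW
P19,HIGH,LOW
P20,HIGH,LOW
P21,HIGH,LOW
P22,HIGH,LOW
P23,MODERATE,LOW
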