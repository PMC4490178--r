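vowel,mode,mouth_area_mm2,wall_area_mm2,length_cm
a,singing,830.8,20287,18.81
a,speech,360.4,16261,16.96
i,singing,317.0,18103,17.35
i,speech,380.5,16096,16.28
oe,singing,214.4,19035,18.30
oe,speech,115.2,20656,18.43
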