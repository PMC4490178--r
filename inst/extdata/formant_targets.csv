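vowel,mode,k,F_khz,BW_hz
a,singing,1,0.555,68
a,singing,2,1.120,33
a,singing,3,2.468,69
a,singing,4,2.737,74
a,singing,5,3.301,140
a,speech,1,0.564,49
a,speech,2,1.120,44
a,speech,3,2.468,69
a,speech,4,3.089,79
a,speech,5,3.473,142
i,singing,1,0.360,49
i,singing,2,1.700,38
i,singing,3,2.313,59
i,singing,4,2.827,74
i,singing,5,3.751,135
i,speech,1,0.312,33
i,speech,2,1.796,54
i,speech,3,2.292,82
i,speech,4,2.925,100
i,speech,5,3.348,113
oe,singing,1,0.409,38
oe,singing,2,1.356,42
oe,singing,3,2.533,67
oe,singing,4,2.819,79
oe,singing,5,3.301,140
oe,speech,1,0.379,36
oe,speech,2,1.218,42
oe,speech,3,2.469,79
oe,speech,4,2.928,82
oe,speech,5,3.873,186
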