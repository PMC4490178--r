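parameter,unit,min,max
m_over_A,g_per_m2,252,251189
b_over_A,N_s_per_m3,65,450000
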