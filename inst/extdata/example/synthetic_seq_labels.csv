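"id","group"
"g1_s1","g1"
"g1_s2","g1"
"g1_s3","g1"
"g1_s4","g1"
"g1_s5","g1"
"g1_s6","g1"
"g2_s1","g2"
"g2_s2","g2"
"g2_s3","g2"
"g2_s4","g2"
"g2_s5","g2"
"g2_s6","g2"
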