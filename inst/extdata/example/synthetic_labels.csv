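"id","species","site","colony","replicate_id"
"sp1_st1_i1_r1","sp1","site1","sp1_st1_i1","r1"
"sp1_st1_i1_r2","sp1","site1","sp1_st1_i1","r2"
"sp1_st1_i2_r1","sp1","site1","sp1_st1_i2","r1"
"sp1_st1_i2_r2","sp1","site1","sp1_st1_i2","r2"
"sp1_st1_i3_r1","sp1","site1","sp1_st1_i3","r1"
"sp1_st1_i3_r2","sp1","site1","sp1_st1_i3","r2"
"sp2_st1_i1_r1","sp2","site1","sp2_st1_i1","r1"
"sp2_st1_i1_r2","sp2","site1","sp2_st1_i1","r2"
"sp2_st1_i2_r1","sp2","site1","sp2_st1_i2","r1"
"sp2_st1_i2_r2","sp2","site1","sp2_st1_i2","r2"
"sp2_st1_i3_r1","sp2","site1","sp2_st1_i3","r1"
"sp2_st1_i3_r2","sp2","site1","sp2_st1_i3","r2"
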