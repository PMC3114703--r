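experiment,total,common_all,specific_v,specific_vf,specific_vfa,pair_vfa_vf,pair_v_vf,pair_v_vfa
LA1,37,16,0,0,4,3,7,7
LA2,31,13,1,2,2,2,6,5
LB1,34,18,3,1,2,5,3,2
LB2,31,13,1,0,1,7,5,4
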