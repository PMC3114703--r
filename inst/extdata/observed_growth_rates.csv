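experiment,treatment,horizon_h,growth_rate,growth_sd
LA1,VFA,48,0.12,0.05
LA1,VFA,96,0.14,0.01
LA1,VF,48,0.09,0.06
LA1,VF,96,0.10,0.06
LA1,V,48,0.09,0.06
LA1,V,96,0.08,0.05
LA2,VFA,48,0.30,0.10
LA2,VFA,96,0.37,0.03
LA2,VF,48,0.36,0.36
LA2,VF,96,0.39,0.01
LA2,V,48,0.28,0.03
LA2,V,96,0.47,0.04
LB1,VFA,48,0.27,0.02
LB1,VFA,96,0.28,0.01
LB1,VF,48,0.27,0.00
LB1,VF,96,0.23,0.00
LB1,V,48,0.18,0.01
LB1,V,96,0.18,0.01
LB2,VFA,48,0.68,0.10
LB2,VFA,96,0.73,0.01
LB2,VF,48,0.65,0.02
LB2,VF,96,0.62,0.01
LB2,V,48,0.47,0.10
LB2,V,96,0.51,0.01
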