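experiment,treatment,variable,t0,tfinal
LA1,V,picocyano,0.1e4,0.3e4
LA1,V,pnf,0,0
LA1,V,hnf,0,0
LA1,VFA,picocyano,6.5e4,7.5e4
LA1,VFA,pnf,4.5e2,4.8e2
LA1,VFA,hnf,6.2e2,8.1e2
LA1,VF,picocyano,5.5e4,2.4e4
LA1,VF,pnf,4.2e2,6.6e2
LA1,VF,hnf,6.5e2,8.0e2
LA2,V,picocyano,0.8e4,0.3e4
LA2,V,pnf,0,0
LA2,V,hnf,0,0
LA2,VFA,picocyano,10.2e4,15.8e4
LA2,VFA,pnf,14.4e2,28.5e2
LA2,VFA,hnf,5.6e2,11.1e2
LA2,VF,picocyano,11.2e4,6.3e4
LA2,VF,pnf,14.0e2,19.1e2
LA2,VF,hnf,5.4e2,13.5e2
LB1,V,picocyano,0,0
LB1,V,pnf,0,0
LB1,V,hnf,0,0
LB1,VFA,picocyano,0.8e4,1.5e4
LB1,VFA,pnf,1.3e2,8.7e2
LB1,VFA,hnf,2.5e2,12.0e2
LB1,VF,picocyano,0.7e4,0.4e4
LB1,VF,pnf,1.1e2,6.5e2
LB1,VF,hnf,2.9e2,12.4e2
LB2,V,picocyano,0.3e4,0.5e4
LB2,V,pnf,0,0
LB2,V,hnf,0,0
LB2,VFA,picocyano,7.3e4,16.6e4
LB2,VFA,pnf,2.5e2,7.5e2
LB2,VFA,hnf,3.6e2,20.7e2
LB2,VF,picocyano,7.1e4,3.1e4
LB2,VF,pnf,3.1e2,12.5e2
LB2,VF,hnf,3.9e2,13.8e2
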