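experiment,variable,value,sd
LA1,bacteria,2.44e6,0.3e5
LA1,viruses,3.7e7,0.1e7
LA1,hnf,7.5e2,1.3e2
LA1,pnf,4.9e2,1.3e2
LA1,picocyano,9.0e4,0.5e4
LA2,bacteria,1.23e6,0.4e5
LA2,viruses,5.1e7,0.4e7
LA2,hnf,6.9e2,0.6e2
LA2,pnf,18.0e2,3.1e2
LA2,picocyano,15.0e4,1.1e4
LB1,bacteria,3.50e6,1.2e5
LB1,viruses,8.3e7,0.3e7
LB1,hnf,2.6e2,1.3e2
LB1,pnf,1.4e2,0.2e2
LB1,picocyano,2.0e4,0.1e4
LB2,bacteria,2.52e6,2.0e5
LB2,viruses,15.3e7,0.7e7
LB2,hnf,3.9e2,1.5e2
LB2,pnf,2.9e2,0.5e2
LB2,picocyano,12.0e4,0.8e4
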