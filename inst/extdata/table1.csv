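variable,mean,se,min,max,cv
MAT,6.67,0.22,4.1,10.3,27
MAP,636.8,11.29,554,889,15
TSN,2.48,0.22,0.9,9.6,71
TSK,19.57,0.31,14.1,25.9,13
TSP,0.52,0.02,0.2,1.3,39
SLA,13.81,0.43,7.5,28.4,27
LS,35.82,1.35,19.5,72.4,28
LDW,2.7,0.2,2.7,10.2,30
Nmass,23.59,0.41,17.6,33.7,15
Narea,1.79,0.05,1,3.1,22
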