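variable,Nmass,Narea,SLA,LS,LDW,TSN,TSK,TSP,MAT,MAP
Nmass,1,0.064,0.63,0.39,-0.03,-0.23,0.18,-0.07,-0.17,-0.21
Narea,0.064,1,-0.63,-0.17,0.45,0.05,0.55,0.27,-0.04,-0.17
SLA,0.63,-0.63,1,0.35,-0.37,-0.19,-0.24,-0.27,-0.14,-0.01
LS,0.39,-0.17,0.35,1,0.69,-0.07,0.03,-0.01,-0.11,-0.03
LDW,-0.03,0.45,-0.37,0.69,1,0.09,0.28,0.24,-0.06,-0.02
TSN,-0.23,0.05,-0.19,-0.07,0.09,1,-0.08,0.03,-0.07,0.59
TSK,0.18,0.55,-0.24,0.03,0.28,-0.08,1,0.58,0.09,-0.53
TSP,-0.07,0.27,-0.27,-0.01,0.24,0.03,0.58,1,0.13,-0.36
MAT,-0.17,-0.04,-0.14,-0.11,-0.06,-0.07,0.09,0.13,1,-0.34
MAP,-0.21,-0.17,-0.01,-0.03,-0.02,0.59,-0.53,-0.36,-0.34,1
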