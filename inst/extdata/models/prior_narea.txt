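latent LMT: SLA LS LDW
path MAT -> TSN
path MAT -> TSK
path MAT -> TSP
path MAP -> TSN
path MAP -> TSK
path MAP -> TSP
path MAT -> LMT
path MAP -> LMT
path MAT -> Narea
path MAP -> Narea
path TSN -> LMT
path TSK -> LMT
path TSP -> LMT
path TSN -> Narea
path TSK -> Narea
path TSP -> Narea
path LMT -> Narea
cov MAT ~~ MAP
cov TSN ~~ TSK
cov TSN ~~ TSP
cov TSK ~~ TSP
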