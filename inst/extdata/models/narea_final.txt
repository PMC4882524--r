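latent LMT2: SLA LDW
path MAP -> TSK
path MAP -> TSP
path TSP -> LMT2
path TSP -> Narea
path TSK -> Narea
path LMT2 -> Narea
cov TSK ~~ TSP
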