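# Default phenotype signatures for phenotype statistics.
# Format: Name = (node=bit, node=bit, ...)
CIP = (ApicalBasal_Pol=1, YAP=0, TAZ=0)
noCIP = (ApicalBasal_Pol=0, YAP=1, TAZ=1)
Migratory = (Fast_Migration=1)
Non-migratory = (Fast_Migration=0)
Epithelial = (miR_34=1, miR_200=1, Ecadherin_mRNA=1, ZEB1_H=0)
Mesenchymal = (miR_34=0, miR_200=0, Ecadherin_mRNA=0, ZEB1_H=1, N_bcatenin_H=1)
Hybrid_EM = (miR_34=0, miR_200=1, Ecadherin_mRNA=1, ZEB1_H=0, ZEB1=1, SNAI1=1)
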