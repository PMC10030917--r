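# Isolated EMT regulatory switch (tri-stable: epithelial / hybrid E/M /
# mesenchymal).  Former external inputs (GSK3beta, NF-kB, Pak1, junction
# context) are substituted at their frozen permissive values, so the
# module is self-contained with a single environment context.
miR_34 *= not (SNAI1 or ZEB1)
miR_200 *= not ZEB1_H and (miR_200 or not (SNAI1 and Twist1 and ZEB1))
SNAI1 *= not miR_34
Twist1 *= SNAI1
SNAI2 *= Twist1 or N_bcatenin_H
ZEB1 *= SNAI2 or ZEB1_H
ZEB1_H *= ZEB1 and N_bcatenin_H
N_bcatenin *= not miR_34
N_bcatenin_H *= N_bcatenin and not miR_200
Ecadherin_mRNA *= not (SNAI1 and ZEB1_H)
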