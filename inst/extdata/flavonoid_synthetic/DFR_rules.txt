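# DFR rules; the specificity line anchors the 26-aa substrate-binding
# domain at reference position 131, so domain position 3 is residue 133
133 N DFR-substrate-position-3
specificity	131	3	N=accepts dihydrokaempferol, dihydroquercetin and dihydromyricetin	D=reduced dihydrokaempferol acceptance	L=dihydrokaempferol preference, reduced dihydromyricetin processing	A=dihydrokaempferol preference, reduced dihydromyricetin processing
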