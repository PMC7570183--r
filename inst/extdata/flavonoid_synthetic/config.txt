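# reaction  bait_fasta  reference_id  rules_table
CHS	CHS.fasta	CHS_syn_01	CHS_rules.txt
DFR	DFR.fasta	DFR_syn_01	DFR_rules.txt
FLS	FLS.fasta	FLS_syn_01	FLS_rules.txt
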