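#!/usr/bin/env Rscript
# Regenerates the synthetic flavonoid knowledge base shipped under
# inst/extdata/flavonoid_synthetic/. The bait families are simulated (the
# curated collections this emulates are assembled by hand from literature
# evidence and are not redistributed here); the documented diagnostic
# residues and domain spans are planted at their published positions so the
# residue screen exercises the real rule set. Deterministic: fixed seeds.

library(pathenz)

out <- file.path("inst", "extdata", "flavonoid_synthetic")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

n <- 6; div <- 0.1

# CHS: chalcone synthase, diagnostic Q166/Q167, malonyl-CoA motif 313-329.
chs <- make_family(n, 395, div, diagnostics = list(c("166", "Q"), c("167", "Q")),
                   seed = 20101, prefix = "CHS_syn")
# STS: stilbene synthase relatives sharing the CHS ancestor (same seed ->
# same ancestor) but with H at position 167 -- the contrasting family.
sts <- make_family(n, 395, div, diagnostics = list(c("166", "Q"), c("167", "H")),
                   seed = 20101, prefix = "STS_syn")
# DFR: dihydroflavonol 4-reductase; N at position 3 of the 26-aa
# substrate-binding domain (anchored at reference position 131 here).
dfr <- make_family(n, 340, div, diagnostics = list(c("133", "N")),
                   seed = 20202, prefix = "DFR_syn")
# FLS: flavonol synthase (2-ODD family), two planted catalytic residues.
fls <- make_family(n, 330, div, diagnostics = list(c("220", "H"), c("222", "D")),
                   seed = 20303, prefix = "FLS_syn")

write_fasta(chs$seqs, file.path(out, "CHS.fasta"))
write_fasta(sts$seqs, file.path(out, "STS.fasta"))
write_fasta(dfr$seqs, file.path(out, "DFR.fasta"))
write_fasta(fls$seqs, file.path(out, "FLS.fasta"))

writeLines(c(
  "# CHS residue/domain rules (positions on the designated reference)",
  "166 Q CHS-diagnostic-Q166",
  "167 Q CHS-diagnostic-Q167",
  "313-329 malonyl-CoA-binding-motif 0.6"
), file.path(out, "CHS_rules.txt"))

writeLines(c(
  "# DFR rules; the specificity line anchors the 26-aa substrate-binding",
  "# domain at reference position 131, so domain position 3 is residue 133",
  "133 N DFR-substrate-position-3",
  paste("specificity", "131", "3",
        "N=accepts dihydrokaempferol, dihydroquercetin and dihydromyricetin",
        "D=reduced dihydrokaempferol acceptance",
        "L=dihydrokaempferol preference, reduced dihydromyricetin processing",
        "A=dihydrokaempferol preference, reduced dihydromyricetin processing",
        sep = "\t")
), file.path(out, "DFR_rules.txt"))

writeLines(c(
  "# FLS rules",
  "220 H FLS-FeII-binding",
  "222 D FLS-FeII-binding"
), file.path(out, "FLS_rules.txt"))

writeLines(c(
  "# reaction  bait_fasta  reference_id  rules_table",
  paste("CHS", "CHS.fasta", names(chs$seqs)[1], "CHS_rules.txt", sep = "\t"),
  paste("DFR", "DFR.fasta", names(dfr$seqs)[1], "DFR_rules.txt", sep = "\t"),
  paste("FLS", "FLS.fasta", names(fls$seqs)[1], "FLS_rules.txt", sep = "\t")
), file.path(out, "config.txt"))

cat("knowledge base written to", out, "\n")
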