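# pathenz

Knowledge-based identification of pathway enzymes in plant sequence data.

Annotating the enzymes of a metabolic pathway in a newly sequenced plant
genome or transcriptome is harder than a BLAST search suggests: the
interesting enzyme families (chalcone synthases vs. stilbene synthases,
F3'H vs. F3'5'H hydroxylases, the 2-ODD family) contain members that are
nearly identical in overall sequence but differ at a handful of
catalytically decisive residues. `pathenz` screens peptide, transcript, or
genome sequences against curated per-reaction **bait** sequences, refines
the candidates by global alignment and nearest-bait phylogenetic
classification, and then inspects **functionally relevant amino-acid
residues and domains** on a designated reference to predict whether each
candidate encodes a functional enzyme.

## Method in brief

For baits *B* of one reaction and subject *s*, a local alignment hit
(BLOSUM62, gap 11/1) is kept when

```
identity(s, b) > 0.40   and   score(s, b) / selfscore(b) > 0.30
```

where `selfscore(b)` is the substitution-matrix diagonal summed over the
bait (its gap-free self-alignment score). Surviving candidates are aligned
globally with their baits; alignment columns with non-gap fraction < 0.1
are removed before a neighbor-joining tree is built, and each candidate
inherits the reaction of its minimum-patristic-distance bait (global
alignment similarity when no tree is possible). Finally, reference residue
positions (e.g. the CHS-diagnostic Q166/Q167), domain spans (e.g. a
malonyl-CoA-binding motif at reference positions 313–329) and
substrate-specificity positions (e.g. N/D/L/A at position 3 of the DFR
substrate-binding domain) are mapped through the alignment onto every
candidate; a candidate is predicted `functional` only if **all** checked
positions match.

Three input modes converge on that peptide path:

* **pep** — peptides screened directly;
* **rna** — six-frame translation into stop-free fragments (≥ 50 aa);
* **dna** — translated search against the genome, hits grouped into loci,
  and **one isoform per locus** stitched so that every intron is a
  canonical `GT..AG` on the coding strand and the spliced CDS stays in
  frame without stops; loci with no canonical interpretation are flagged
  `non-canonical-or-partial`, never stitched through. Gene models are
  exported as GFF3 plus CDS/peptide FASTA.

A synthetic flavonoid knowledge base (CHS/DFR/FLS bait families plus an STS
contrast family, with the documented diagnostic residues planted at their
published positions) ships under `inst/extdata/flavonoid_synthetic/` — the
sequences are simulated, as the curated collections this emulates are
assembled by hand from literature evidence. The `fixtures` module
(`make_family()`, `make_genome()`, `make_fixture_suite()`) generates
arbitrary families, mutants, transcripts, and multi-exon genomes with known
planted truth.

## Worked example

```r
library(pathenz)

fixture_dir <- file.path(tempdir(), "demo")
fx  <- make_fixture_suite(fixture_dir, seed = 42)   # 3 reactions + planted truth
cfg <- run_config(mode    = "pep",
                  subject = file.path(fixture_dir, "subjects_pep.fasta"),
                  config  = fx$config,
                  out     = file.path(fixture_dir, "out"))
res <- run_pipeline(cfg)
res$summary[, c("reaction", "candidate_id", "closest_bait_id",
                "value", "n_rules", "n_matched", "prediction")]
```

```
  reaction   candidate_id closest_bait_id     value n_rules n_matched             prediction
1      CHS    cand_CHS_07          CHS_05 0.1653584       3         3             functional
2      CHS cand_CHS_Q167H          CHS_05 0.1661289       3         2 possibly_nonfunctional
3      CHS    cand_CHS_08          CHS_05 0.1730223       3         3             functional
4      DFR    cand_DFR_08          DFR_01 0.1470588       2         2             functional
5      DFR    cand_DFR_07          DFR_01 0.1730474       2         2             functional
6      FLS    cand_FLS_08          FLS_05 0.1503534       3         3             functional
7      FLS    cand_FLS_07          FLS_05 0.1736581       3         3             functional
```

Each row is one surviving candidate: the reaction it was assigned to, its
closest bait and tree distance (`value`), how many residue/domain rules were
checked and matched, and the functionality prediction. The planted Q167H
mutant is the one `possibly_nonfunctional` call, and its notes name the
violated rule:

```r
res$summary$notes[res$summary$candidate_id == "cand_CHS_Q167H"]
#> [1] "CHS-diagnostic: expected [Q] at reference position 167, observed H (mismatch)"
```

The output directory additionally holds, per reaction, the candidate FASTA,
the alignment, the NJ tree (Newick), and residue/domain report TSVs, plus a
global `summary.tsv` and a stage-by-stage `log.tsv` with in/out counts
(genome mode adds `models.gff3` and `cds.fasta`).

A thin command-line front end over the same functions lives at
`inst/scripts/pathenz`:

```sh
pathenz annotate --mode dna --subject genome.fasta \
    --config inst/extdata/flavonoid_synthetic/config.txt --out out/
pathenz contrast --set-a CHS.fasta --set-b STS.fasta --purity 0.9
pathenz fixtures --out fixtures/ --seed 1
```

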