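---
title: "Knowledge-based screening for pathway enzymes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based screening for pathway enzymes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathenz)
```

## The problem

Given a new plant genome, transcriptome, or predicted proteome, which
sequences encode the enzymes of a metabolic pathway of interest — and are
they likely to be functional? BLAST-style similarity alone answers the first
question poorly for enzyme families whose members are nearly identical in
overall sequence but differ in a handful of catalytically decisive residues:
chalcone synthase (CHS) and stilbene synthase share most of their sequence,
yet an *Arabidopsis thaliana*-numbered Q166/Q167 pair distinguishes a
chalcone synthase from a stilbene synthase (Q166 H167 or H166 Q167).

`pathenz` implements a knowledge-based screening procedure around exactly
this observation. The knowledge is supplied per reaction of the pathway:

* a **bait set** — one peptide FASTA of previously characterised enzymes for
  that reaction, one of which is the designated **reference**;
* a **rules table** — functionally relevant residue positions, domain spans,
  and optional substrate-specificity readouts, all 1-based on the reference.

A synthetic flavonoid-pathway knowledge base ships under
`inst/extdata/flavonoid_synthetic/` (see *Shipped data* below).

## The procedure

For all three input modes the analysis converges on a peptide path:

1. **Candidate collection.** Subjects are aligned locally (BLOSUM62, gap
   open 11 / extend 1) against every bait. A hit survives when its identity
   over aligned columns exceeds `min_identity` (default 0.40) **and** its
   score exceeds `min_score_ratio` (default 0.30) of the bait's
   self-alignment score — the sum of the substitution-matrix diagonal over
   the bait, computed by `self_score()`. Both comparisons are strict
   (`>`): a hit at exactly 40% identity is rejected. These deliberately
   lenient thresholds collect a comprehensive candidate set; the later
   alignment- and tree-based steps do the discriminating.
2. **Refinement.** Candidates and baits are aligned globally (`build_msa()`;
   MAFFT when on the PATH, otherwise an internal center-star progressive
   alignment). For tree building, columns with non-gap fraction below
   `min_occupancy` (default 0.1) are removed by `occupancy_filter()`;
   residue mapping always uses the unfiltered alignment so that reference
   coordinates stay intact.
3. **Classification.** Each candidate inherits the reaction of its closest
   bait: by patristic distance on a neighbor-joining tree of p-distances
   (`classify_by_tree()`), or by global-alignment identity
   (`classify_by_similarity()`) when no tree can be built. When the
   `k_nearest` (default 3) nearest baits span several reactions, the
   alternatives are recorded as co-candidates — this is how an enzyme that
   resembles two related hydroxylase families is assigned to the family
   with the higher overall bait-set similarity while the other is retained
   as a co-candidate.
4. **Residue and domain screen.** Reference rule positions are mapped
   through the alignment onto each candidate (`map_positions()`), and a
   candidate is predicted `functional` only when **all** checked residue
   positions match an allowed residue and all domains reach their
   conservation threshold; otherwise `possibly_nonfunctional`, with every
   violated rule named. A gapped (absent) diagnostic position is reported
   distinctly and also blocks a `functional` call. Substrate-specificity
   rules (e.g. the DFR position-3 N/D/L/A readout) only append notes and
   never change the prediction.

### Input modes

* `pep` — peptides are screened directly.
* `rna` — transcripts are translated in all six frames; maximal stop-free
  runs of at least `min_fragment_len` residues (default 50) become the
  peptide subjects. Fifty residues suppress the clouds of spurious short
  fragments that six-frame translation produces while retaining any
  realistic coding transcript.
* `dna` — baits are compared against the translated genome. Stop-free
  six-frame fragments (floor 10 residues here, since single exons can be
  much shorter than 50 codons) are aligned locally with iterative masking,
  so several exons inside one fragment are recovered as separate hits; a
  hit whose alignment bridges an in-frame, stop-free intron is split at
  bait-side alignment gaps of 15+ residues. Hits of one bait on one
  contig/strand are chained into loci when gaps stay below
  `max_intron_len` (default 20 000 nt, plant-typical) and bait coordinates
  advance colinearly (up to 30 residues of overlap are tolerated, because
  local alignment overshoots exon edges when the intron's in-frame
  translation resembles the bait).

### Isoform stitching

One isoform per locus is constructed. Exon boundaries may shift by at most
`search_window` nt (default 30, widened by three times the bait-coordinate
overlap of the adjacent hits) from the raw hit edges such that every intron
starts `GT` and ends `AG` on the coding strand, each junction preserves
reading frame (donor and acceptor shifts congruent mod 3), and the spliced
CDS contains no internal stop. Among feasible boundary pairs the one whose
junction-local spliced peptide scores highest against the bait is chosen;
all pairs of one junction are scored over the same outer genomic span so the
comparison reflects only the junction placement, with ties broken by the
smallest total shift, then the leftmost donor. Terminal exons are extended
codon-wise toward full bait coverage unless a stop codon intervenes, which
recovers terminal residues that a local alignment clips when they do not
match the bait. If no canonical, stop-free stitching exists — for example a
GC–AG intron — the locus is demoted to its single best fragment and flagged
`non-canonical-or-partial`, never silently dropped and never stitched
through a non-canonical site. Restricting splice sites to GT–AG is a
deliberate scope decision: non-canonical sites are rare in plant genomes and
searching for them would multiply both cost and mis-annotation risk.

When several baits of one reaction produce models for the same genomic
region, the models are ranked by alignment score against the reaction's
reference — a common yardstick, unlike raw per-bait scores — and ties go to
the shorter peptide (material that does not improve the reference alignment
is unsupported by the knowledge base). In `dna` mode the identity /
self-score-ratio filter is applied to the assembled isoform rather than to
raw exon fragments, whose per-exon ratios would almost always fail.

## Tunable parameters

| parameter          | default | unit      | role |
|--------------------|---------|-----------|------|
| `min_identity`     | 0.40    | fraction  | candidate filter, strict `>` |
| `min_score_ratio`  | 0.30    | fraction  | score / bait self-score, strict `>` |
| `min_occupancy`    | 0.1     | fraction  | alignment column filter before trees |
| `min_fragment_len` | 50      | residues  | six-frame fragment floor (`rna`) |
| `max_intron_len`   | 20 000  | nt        | locus chaining gap limit |
| `search_window`    | 30      | nt        | splice-boundary search radius |
| `k_nearest`        | 3       | baits     | co-candidate inspection depth |
| `purity`           | 0.9     | fraction  | contrasting-residue support |
| `similar_mode`     | off     | —         | accept biochemically similar residues |

`similar_mode` exists because imperfectly conserved positions often admit
several residues of one biochemical group (aliphatic, aromatic, polar,
acidic, basic); the default stays strict because the functionality criterion
is a *matching* residue at every checked position. The domain conservation
default (`min_identity` 0.6 per domain rule) separates conserved from random
over short motifs and is configurable per rule in the rules table.

## Contrasting-residue discovery

`contrasting_residues()` aligns two families jointly and reports the columns
at which the smallest residue sets covering at least `purity` of each
family's non-gap rows are disjoint, in the coordinates of a designated
reference. At `purity = 1.0` a single aberrant row hides a contrast;
0.9 tolerates one such row in ten. On the shipped synthetic CHS and STS
families it reports exactly the planted Q/H column.

## The synthetic data generator

No real sequence data are redistributed. `make_family()` evolves `n`
peptides from one random (or supplied) ancestor by independent per-site
substitution, pinning diagnostic residues in all members — emulating
functionally constrained sites. `make_genome()` reverse-translates peptides
with uniform codon choice, splits them into exons of at least 10 codons at
codon boundaries, inserts GT–AG introns (length 80–2 000 nt by default,
below `max_intron_len` by construction) and embeds the genes on random
strands in random intergenic sequence, recording all coordinates as truth.
`make_fixture_suite()` wires three reactions (CHS-, DFR-, FLS-like), two
planted candidates each, one planted Q167H mutant, and matched
peptide/transcript/genome subject files.

Deliberate simplifications: substitutions are uniform over the 19
alternatives (no rate matrix, no indels within families), codon usage is
uniform, and intergenic sequence is i.i.d. random. Two related families are
therefore simulated as two ancestors diverged at ~30% of sites with pinned
contrasting diagnostics — families differing *only* at the diagnostic pair
would be inseparable by any distance method, which is also true of the real
enzymes: their overall divergence, not the diagnostic pair, carries the
phylogenetic signal. Consequently, passing fixtures demonstrates correct
bookkeeping, threshold semantics, splice-site logic and classification
behaviour — not performance on real genomes, where gene structure, repeats
and base composition are far less benign.

## Numerical and degenerate-input choices

* Codons containing `N` translate to `X`; `X` never satisfies a residue rule.
* Identity is percent identical over aligned columns including internal
  gaps (the stricter of the common readings of "sequence similarity").
* NJ branch lengths are clamped at zero so patristic distances stay
  non-negative; patristic distance is rooting-invariant, which is why trees
  are not rooted before measuring.
* Classification ties break deterministically (higher raw score, then
  lexicographic bait id); assignments are invariant under candidate
  permutation.
* Fewer than 4 leaves, or a failed tree: classification falls back to
  global-alignment similarity with a warning.
* Empty rule tables yield a vacuously `functional` call carrying an explicit
  caveat note.
* The pipeline contains no randomness; reruns with identical inputs are
  byte-identical. The `seed` in a `run_config()` is recorded for provenance
  and used only by the fixture generator.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
fixture suites of three reactions × six baits (~2 000 aa of baits), genomes
of roughly 20–25 kb with 5–7 planted genes of 1–3 exons, and a 200-candidate
two-family classification instance. These sizes exercise every code path —
multi-exon stitching on both strands, paralog disambiguation, mutant
flagging — while keeping a complete three-mode run in the low minutes on a
single core.

## Known limitations

* One isoform per locus; no alternative splicing, no UTRs, no non-canonical
  splice sites (by design).
* Terminal-exon extension assumes the candidate is roughly bait-length; a
  genuinely shorter protein is extended up to the first stop or full bait
  coverage, whichever comes first.
* Tandem paralogs closer than `max_intron_len` can transiently chain into
  one locus; the reference-score ranking resolves the cases the fixtures
  generate, but adversarial arrangements (a pseudogene fragment colinear
  with a neighbour) may still merge.
* The internal center-star aligner is adequate for the within-family
  identities this method operates at (>40%); for distant families MAFFT
  (used automatically when present) is strongly preferable.
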