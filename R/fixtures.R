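# inverse genetic code: amino acid -> codons (standard code)
codons_for <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Generate a synthetic protein family with planted diagnostic residues
#'
#' `n` peptides are derived from one random ancestor by independent per-site
#' substitution at rate `divergence` (substitutions drawn uniformly over the
#' 19 alternatives); the diagnostic positions are pinned to their planted
#' residue in every member, emulating functionally constrained sites.
#'
#' @param n family size (>= 2).
#' @param length peptide length.
#' @param divergence per-site substitution probability per member.
#' @param diagnostics list/data.frame of planted `(position, residue)` pairs,
#'   e.g. `list(c(166, "Q"), c(167, "Q"))`.
#' @param seed integer seed; identical inputs reproduce identical families.
#' @param prefix id prefix (default `"fam"`).
#' @param ancestor optional ancestor peptide string (e.g. a mutated copy of
#'   another family's ancestor, to simulate related enzyme families);
#'   default: drawn uniformly at random.
#' @return list with `seqs` (peptide [seqset()]) and `truth` (list recording
#'   the ancestor, diagnostics, divergence and seed).
#' @export
make_family <- function(n, length, divergence, diagnostics = list(),
                        seed = 1, prefix = "fam", ancestor = NULL) {
  stopifnot(n >= 2, length >= 1, divergence >= 0, divergence <= 1)
  diagnostics <- normalize_diags(diagnostics)
  stopifnot(all(diagnostics$position <= length))
  if (!is.null(ancestor)) stopifnot(nchar(ancestor) == length)
  withr_seed(seed, {
    ancestor <- if (is.null(ancestor)) sample(AA_ALPHABET, length, replace = TRUE)
                else strsplit(toupper(ancestor), "")[[1]]
    ancestor[diagnostics$position] <- diagnostics$residue
    seqs <- vapply(seq_len(n), function(i) {
      s <- ancestor
      mut <- stats::runif(length) < divergence
      mut[diagnostics$position] <- FALSE
      if (any(mut)) {
        s[mut] <- vapply(s[mut], function(aa)
          sample(setdiff(AA_ALPHABET, aa), 1), character(1))
      }
      paste(s, collapse = "")
    }, character(1))
    names(seqs) <- sprintf("%s_%02d", prefix, seq_len(n))
    list(seqs = seqset(seqs, kind = "peptide"),
         truth = list(ancestor = paste(ancestor, collapse = ""),
                      diagnostics = diagnostics, divergence = divergence,
                      seed = seed))
  })
}

normalize_diags <- function(diagnostics) {
  if (is.data.frame(diagnostics)) return(diagnostics)
  if (length(diagnostics) == 0) {
    return(data.frame(position = integer(), residue = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(position = as.integer(vapply(diagnostics, `[`, character(1), 1)),
             residue = toupper(vapply(diagnostics, `[`, character(1), 2)),
             stringsAsFactors = FALSE)
}

# evaluate expr under a local RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Apply exact point mutations to a peptide
#'
#' @param seq peptide string (optionally named).
#' @param edits list of `(position, residue)` pairs as in [make_family()].
#' @return the edited sequence (name preserved).
#' @export
make_mutant <- function(seq, edits) {
  s <- strsplit(toupper(as.character(seq)[[1]]), "")[[1]]
  edits <- normalize_diags(edits)
  if (nrow(edits) && any(edits$position < 1 | edits$position > length(s))) {
    stop("edit position out of range (sequence length ", length(s), ")")
  }
  s[edits$position] <- edits$residue
  out <- paste(s, collapse = "")
  names(out) <- names(seq)[1]
  out
}

random_dna <- function(n) paste(sample(DNA_ALPHABET, n, replace = TRUE),
                                collapse = "")

# random intron with canonical GT..AG ends. Non-canonical donors get a
# G-free body so that the planted intron offers no internal GT/AG that a
# canonical-only stitcher could latch onto (the point of planting one is
# that no canonical interpretation exists).
random_intron <- function(len, donor = "GT", acceptor = "AG") {
  stopifnot(len >= 6)
  body <- if (donor == "GT") random_dna(len - 4) else
    paste(sample(c("A", "C", "T"), len - 4, replace = TRUE), collapse = "")
  paste0(donor, body, acceptor)
}

reverse_translate <- function(pep) {
  tab <- codons_for()
  aa <- strsplit(pep, "")[[1]]
  paste(vapply(aa, function(a) {
    cs <- tab[[a]]
    if (is.null(cs)) stop("cannot reverse-translate residue ", a)
    sample(cs, 1)
  }, character(1)), collapse = "")
}

#' Plant multi-exon genes in a synthetic genome
#'
#' Each peptide is reverse-translated with uniform codon choice, split into
#' exons at codon boundaries, separated by random introns starting `GT` and
#' ending `AG` on the coding strand, and embedded (on a random strand) in
#' random intergenic sequence. All planted coordinates are recorded as truth.
#'
#' @param genes list of entries `list(id=, peptide=, n_exons=)`; peptides must
#'   not contain internal stops and be at least `10 * n_exons` residues.
#' @param intergenic_len random sequence length between/around genes
#'   (default 2000).
#' @param intron_len_range intron length range in nt (default `c(80, 2000)`).
#' @param seed integer seed.
#' @param contig_id contig name (default `"chr1"`).
#' @param noncanonical_for gene ids whose first intron gets a `GC` donor
#'   instead of `GT` (to plant a non-canonical splice site).
#' @return list with `genome` (dna [seqset()] of one contig) and `truth`
#'   (per gene: strand, exon and intron forward-strand coordinates, cds,
#'   peptide, splice dinucleotides).
#' @export
make_genome <- function(genes, intergenic_len = 2000,
                        intron_len_range = c(80, 2000), seed = 1,
                        contig_id = "chr1", noncanonical_for = character(0)) {
  withr_seed(seed, {
    pieces <- character(0)
    pos <- 0L
    truth <- list()
    add <- function(s) {
      pieces[[length(pieces) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    add(random_dna(intergenic_len))
    for (g in genes) {
      id <- g$id; pep <- toupper(g$peptide); n_exons <- g$n_exons
      stopifnot(n_exons >= 1, nchar(pep) >= n_exons * 10)
      if (grepl("*", pep, fixed = TRUE)) stop("peptide contains a stop: ", id)
      cds <- reverse_translate(pep)
      n_cod <- nchar(cds) / 3
      # exon cut points at codon boundaries, every exon at least 10 codons
      cuts <- if (n_exons > 1) {
        repeat {
          cuts <- sort(sample(seq(10, n_cod - 10), n_exons - 1))
          if (all(diff(c(0, cuts, n_cod)) >= 10)) break
        }
        cuts
      } else integer(0)
      bounds <- c(0, cuts, n_cod) * 3
      exon_seqs <- substring(cds, bounds[-length(bounds)] + 1, bounds[-1])
      strand <- sample(c("+", "-"), 1)
      coding <- character(0)
      exon_loc <- matrix(0L, nrow = n_exons, ncol = 2)
      intron_loc <- if (n_exons > 1) matrix(0L, nrow = n_exons - 1, ncol = 2)
                    else matrix(0L, 0, 2)
      splice <- character(0)
      at <- 0L
      for (i in seq_len(n_exons)) {
        exon_loc[i, ] <- c(at + 1L, at + nchar(exon_seqs[i]))
        coding <- c(coding, exon_seqs[i])
        at <- at + nchar(exon_seqs[i])
        if (i < n_exons) {
          ilen <- sample(intron_len_range[1]:intron_len_range[2], 1)
          donor <- if (id %in% noncanonical_for && i == 1) "GC" else "GT"
          intr <- random_intron(ilen, donor = donor)
          splice <- c(splice, paste0(donor, "..AG"))
          intron_loc[i, ] <- c(at + 1L, at + ilen)
          coding <- c(coding, intr)
          at <- at + ilen
        }
      }
      gene_coding <- paste(coding, collapse = "")
      glen <- nchar(gene_coding)
      gene_fwd <- if (strand == "+") gene_coding else reverse_complement(gene_coding)
      to_fwd <- function(m) {
        if (nrow(m) == 0) return(data.frame(start = integer(), end = integer()))
        if (strand == "+") {
          data.frame(start = pos + m[, 1], end = pos + m[, 2])
        } else {
          out <- data.frame(start = pos + glen - m[, 2] + 1L,
                            end = pos + glen - m[, 1] + 1L)
          out[order(out$start), , drop = FALSE]
        }
      }
      truth[[id]] <- list(id = id, strand = strand, peptide = pep, cds = cds,
                          exons = to_fwd(exon_loc), introns = to_fwd(intron_loc),
                          splice = splice, n_exons = n_exons)
      add(gene_fwd)
      add(random_dna(intergenic_len))
    }
    genome <- seqset(stats::setNames(paste(pieces, collapse = ""), contig_id),
                     kind = "dna")
    list(genome = genome, truth = truth)
  })
}

#' Transcripts for planted genes
#'
#' Returns the spliced coding sequences of a [make_genome()] truth set as a
#' transcript (dna) [seqset()], for exercising `rna` mode against the same
#' ground truth.
#'
#' @param truth the `truth` element returned by [make_genome()].
#' @return dna [seqset()] of spliced CDS sequences.
#' @export
transcripts_from_truth <- function(truth) {
  seqs <- vapply(truth, function(g) g$cds, character(1))
  names(seqs) <- paste0(vapply(truth, function(g) g$id, character(1)), "_t")
  seqset(seqs, kind = "dna")
}

#' Generate the full synthetic fixture suite on disk
#'
#' Writes a miniature three-reaction knowledge base (bait FASTA + rules
#' tables + config) and matching peptide, transcript and genome subject
#' files with planted true candidates, one planted diagnostic-residue mutant
#' and a truth JSON. Everything derives deterministically from `seed`.
#'
#' @param dir output directory (created).
#' @param seed integer seed.
#' @param n_baits baits per reaction (default 6).
#' @param divergence within-family divergence (default 0.1).
#' @param intron_len_range passed to [make_genome()] (default `c(80, 300)`
#'   to keep the fixture genome compact).
#' @return invisibly, a list with paths and the truth.
#' @export
make_fixture_suite <- function(dir, seed = 1, n_baits = 6, divergence = 0.1,
                               intron_len_range = c(80, 300)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # three reactions of the shipped default pathway, with the documented
  # diagnostic positions of the first one planted
  fams <- list(
    CHS = list(length = 395, diagnostics = list(c("166", "Q"), c("167", "Q"))),
    DFR = list(length = 340, diagnostics = list(c("136", "N"))),
    FLS = list(length = 330, diagnostics = list(c("220", "H"), c("222", "D")))
  )
  kb_dir <- file.path(dir, "baits"); dir.create(kb_dir, showWarnings = FALSE)
  subj_pep <- character(0)
  truth <- list(reactions = list(), seed = seed)
  cfg <- character(0)
  genes <- list()
  i <- 0
  for (rxn in names(fams)) {
    i <- i + 1
    f <- fams[[rxn]]
    fam <- make_family(n_baits + 2, f$length, divergence,
                       diagnostics = f$diagnostics, seed = seed + i * 101,
                       prefix = rxn)
    seqs <- fam$seqs
    bait_ids <- names(seqs)[seq_len(n_baits)]
    cand_ids <- names(seqs)[(n_baits + 1):(n_baits + 2)]
    write_fasta(seqs[bait_ids], file.path(kb_dir, paste0(rxn, ".fasta")))
    rules <- c(sprintf("%s %s %s-diagnostic", fam$truth$diagnostics$position,
                       fam$truth$diagnostics$residue, rxn),
               sprintf("%d-%d %s-core-domain 0.6", 50, 120, rxn))
    writeLines(rules, file.path(kb_dir, paste0(rxn, "_rules.txt")))
    cfg <- c(cfg, sprintf("%s\tbaits/%s.fasta\t%s\tbaits/%s_rules.txt",
                          rxn, rxn, bait_ids[1], rxn))
    cand <- stats::setNames(unclass(seqs[cand_ids]),
                            paste0("cand_", cand_ids))
    subj_pep <- c(subj_pep, cand)
    for (ci in seq_along(cand)) {
      genes[[length(genes) + 1L]] <- list(id = names(cand)[ci],
                                          peptide = cand[[ci]],
                                          n_exons = 1 + (ci %% 3))
    }
    truth$reactions[[rxn]] <- list(
      baits = bait_ids, candidates = names(cand),
      diagnostics = fam$truth$diagnostics)
  }
  # one planted diagnostic mutant of the first CHS candidate
  mut_src <- subj_pep[[truth$reactions$CHS$candidates[1]]]
  mut <- make_mutant(mut_src, list(c("167", "H")))
  subj_pep <- c(subj_pep, stats::setNames(mut, "cand_CHS_Q167H"))
  genes[[length(genes) + 1L]] <- list(id = "cand_CHS_Q167H", peptide = mut,
                                      n_exons = 2)
  truth$mutant <- list(id = "cand_CHS_Q167H", reaction = "CHS",
                       edit = "Q167H")
  writeLines(cfg, file.path(dir, "config.txt"))
  write_fasta(subj_pep, file.path(dir, "subjects_pep.fasta"))
  gen <- make_genome(genes, intergenic_len = 1500,
                     intron_len_range = intron_len_range, seed = seed + 997)
  write_fasta(gen$genome, file.path(dir, "subjects_genome.fasta"))
  tx <- transcripts_from_truth(gen$truth)
  write_fasta(tx, file.path(dir, "subjects_rna.fasta"))
  truth$genome <- gen$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(dir = dir, config = file.path(dir, "config.txt"),
                 truth = truth))
}
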