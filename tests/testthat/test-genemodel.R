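dna_hit <- function(q, s1, s2, q1, q2, score = 100, strand = "+",
                    contig = "chr1") {
  h <- data.frame(query_id = q, subject_id = contig, identity = 0.9,
                  score = score, self_score = 500, q_start = q1, q_end = q2,
                  s_start = s1, s_end = s2, strand = strand, frame = 1L,
                  mode = "dna", stringsAsFactors = FALSE)
  class(h) <- c("search_hits", "data.frame")
  h
}

test_that("colinear nearby hits share a locus, distant hits do not", {
  h <- rbind(dna_hit("b", 1000, 1299, 1, 100),
             dna_hit("b", 1800, 2099, 101, 200))
  loci <- group_hits(h)
  expect_length(loci, 1)
  expect_equal(nrow(loci[[1]]$fragments), 2)

  far <- rbind(dna_hit("b", 1000, 1299, 1, 100),
               dna_hit("b", 1e6, 1e6 + 299, 101, 200))
  expect_length(group_hits(far), 2)

  # non-colinear bait coordinates split loci even when the gap is small
  back <- rbind(dna_hit("b", 1000, 1299, 101, 200),
                dna_hit("b", 1800, 2099, 1, 100))
  expect_length(group_hits(back), 2)

  pep <- dna_hit("b", 1, 300, 1, 100); pep$mode <- "pep"
  expect_error(group_hits(pep), "dna-mode")
})

test_that("two planted paralogs on one contig give two loci with the planted exon counts", {
  fam <- make_family(3, 240, 0.05, seed = 31, prefix = "P")
  peps <- unclass(fam$seqs)
  gen <- make_genome(list(list(id = "pA", peptide = peps[[2]], n_exons = 2),
                          list(id = "pB", peptide = peps[[3]], n_exons = 3)),
                     intergenic_len = 1200, intron_len_range = c(80, 200),
                     seed = 32)
  bs <- bait_set("P", fam$seqs[1], names(fam$seqs)[1])
  hits <- search_candidates(bs, gen$genome, mode = "dna")
  loci <- group_hits(hits)
  expect_length(loci, 2)
  counts <- sort(vapply(loci, function(l) nrow(l$fragments), integer(1)))
  expect_equal(counts, c(2L, 3L))
})

test_that("stitching recovers planted exon boundaries exactly on both strands", {
  fam <- make_family(4, 300, 0.08, seed = 11, prefix = "B")
  peps <- unclass(fam$seqs)
  gen <- make_genome(list(list(id = "g1", peptide = peps[[3]], n_exons = 3),
                          list(id = "g2", peptide = peps[[4]], n_exons = 2)),
                     intergenic_len = 1500, intron_len_range = c(80, 300),
                     seed = 42)
  bs <- bait_set("B", fam$seqs[1:2], names(fam$seqs)[1])
  hits <- search_candidates(bs, gen$genome, mode = "dna")
  models <- pathenz:::dedup_models(lapply(group_hits(hits), function(l)
    stitch_isoform(l, gen$genome, bait = bs$baits[[l$query_id]])))
  expect_length(models, 2)
  for (g in gen$truth) {
    m <- models[[which(vapply(models, function(m) m$peptide == g$peptide,
                              logical(1)))]]
    expect_equal(m$status, "complete")
    expect_equal(as.matrix(m$exons), as.matrix(g$exons),
                 ignore_attr = TRUE)
    expect_equal(as.matrix(m$introns), as.matrix(g$introns),
                 ignore_attr = TRUE)
    # every intron is GT..AG on the coding strand
    contig <- gen$genome[[1]]
    for (i in seq_len(nrow(m$introns))) {
      intr <- substring(contig, m$introns$start[i], m$introns$end[i])
      if (m$strand == "-") intr <- unname(reverse_complement(intr))
      expect_equal(substring(intr, 1, 2), "GT")
      expect_equal(substring(intr, nchar(intr) - 1, nchar(intr)), "AG")
    }
    expect_identical(translate_frame(m$cds, 1), m$peptide)
  }
})

test_that("a single-fragment locus becomes a one-exon model without introns", {
  fam <- make_family(2, 120, 0, seed = 12, prefix = "S")
  gen <- make_genome(list(list(id = "s", peptide = unclass(fam$seqs)[[2]],
                               n_exons = 1)),
                     intergenic_len = 700, seed = 13)
  bs <- bait_set("S", fam$seqs[1], names(fam$seqs)[1])
  hits <- search_candidates(bs, gen$genome, mode = "dna")
  models <- lapply(group_hits(hits), stitch_isoform, genome = gen$genome,
                   bait = unclass(fam$seqs)[[1]])
  expect_length(models, 1)
  expect_equal(nrow(models[[1]]$exons), 1)
  expect_equal(nrow(models[[1]]$introns), 0)
  expect_equal(models[[1]]$peptide, gen$truth$s$peptide)
})

test_that("a planted GC-AG intron is demoted to a flagged partial model", {
  case <- make_gcag_case(900)
  hits <- search_candidates(case$bait_set, case$genome, mode = "dna")
  loci <- group_hits(hits)
  models <- lapply(loci, function(l)
    stitch_isoform(l, case$genome, bait = case$bait_set$baits[[l$query_id]]))
  multi <- models[vapply(loci, function(l) nrow(l$fragments) > 1, logical(1))]
  expect_true(length(multi) >= 1)
  expect_true(all(vapply(multi, function(m)
    m$status == "non-canonical-or-partial", logical(1))))
  expect_true(all(vapply(multi, function(m) nrow(m$introns) == 0, logical(1))))
})

test_that("strand symmetry: the reverse-complemented genome yields identical peptides", {
  fam <- make_family(3, 250, 0.05, seed = 14, prefix = "R")
  gen <- make_genome(list(list(id = "r", peptide = unclass(fam$seqs)[[3]],
                               n_exons = 2)),
                     intergenic_len = 900, intron_len_range = c(80, 200),
                     seed = 15)
  bs <- bait_set("R", fam$seqs[1:2], names(fam$seqs)[1])
  run <- function(genome) {
    hits <- search_candidates(bs, genome, mode = "dna")
    models <- pathenz:::dedup_models(lapply(group_hits(hits), function(l)
      stitch_isoform(l, genome, bait = bs$baits[[l$query_id]])))
    sort(vapply(models, `[[`, character(1), "peptide"))
  }
  fwd <- run(gen$genome)
  rev <- run(seqset(stats::setNames(reverse_complement(gen$genome[[1]]),
                                    "chr1"), "dna"))
  expect_identical(fwd, rev)
})

test_that("gene model coordinates round-trip through GFF3", {
  fam <- make_family(2, 200, 0.05, seed = 16, prefix = "G")
  gen <- make_genome(list(list(id = "g", peptide = unclass(fam$seqs)[[2]],
                               n_exons = 3)),
                     intergenic_len = 800, intron_len_range = c(80, 150),
                     seed = 17)
  bs <- bait_set("G", fam$seqs[1], names(fam$seqs)[1])
  hits <- search_candidates(bs, gen$genome, mode = "dna")
  models <- lapply(group_hits(hits), stitch_isoform, genome = gen$genome,
                   bait = unclass(fam$seqs)[[1]])
  tf <- tempfile(fileext = ".gff3")
  write_gff3(models, tf)
  cds <- read_gff3(tf)
  got <- cds[order(cds$start), c("start", "end")]
  want <- models[[1]]$exons[order(models[[1]]$exons$start), ]
  expect_equal(as.matrix(got), as.matrix(want), ignore_attr = TRUE)
  expect_true(all(cds$strand == models[[1]]$strand))
})
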