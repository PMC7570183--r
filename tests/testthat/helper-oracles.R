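# independent oracles and fixture builders used across the test files

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")
random_pep_str <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

# brute-force translation oracle, independent of the package: seqinr's codon
# table, manual reverse complement and frame offsetting
oracle_translate <- function(s, frame) {
  s <- toupper(s)
  if (frame < 0) {
    s <- chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]),
                                        collapse = ""))
  }
  v <- strsplit(substring(s, abs(frame)), "")[[1]]
  n <- (length(v) %/% 3) * 3
  if (n == 0) return("")
  aa <- seqinr::translate(v[1:n], ambiguous = FALSE)
  paste(aa, collapse = "")
}

# one-line predicate oracle for the candidate filter
oracle_filter <- function(hits, mi = 0.40, msr = 0.30) {
  hits[hits$identity > mi & hits$score / hits$self_score > msr, , drop = FALSE]
}

# random hit table spanning both sides of the thresholds, plus exact-boundary
# rows
random_hits <- function(n) {
  h <- data.frame(
    query_id = paste0("q", seq_len(n)), subject_id = paste0("s", seq_len(n)),
    identity = round(runif(n), 3), score = round(runif(n, 1, 100)),
    self_score = 100, q_start = 1L, q_end = 10L, s_start = 1L, s_end = 10L,
    strand = "+", frame = NA_integer_, mode = "pep", stringsAsFactors = FALSE)
  boundary <- h[1:2, ]
  boundary$identity <- c(0.40, 0.95)
  boundary$score <- c(95, 30)   # identity at 0.40 exactly; ratio at 0.30 exactly
  h <- rbind(h, boundary)
  class(h) <- c("search_hits", "data.frame")
  h
}

# two related enzyme families (shared origin, diverged ancestors) with
# contrasting diagnostic residues, as for chalcone vs stilbene synthases
make_family_pair <- function(n_per, len, seed,
                             diag_pos = pmin(c(166, 167), c(len - 1, len)),
                             within = 0.08, between = 0.3) {
  fam_a <- make_family(n_per, len, within,
                       diagnostics = list(c(as.character(diag_pos[1]), "Q"),
                                          c(as.character(diag_pos[2]), "Q")),
                       seed = seed, prefix = "A")
  anc_a <- fam_a$truth$ancestor
  # ancestor of family B: mutated copy of A's ancestor
  set.seed(seed + 7)
  av <- strsplit(anc_a, "")[[1]]
  mut <- runif(length(av)) < between
  av[mut] <- vapply(av[mut], function(x) sample(setdiff(AA20, x), 1),
                    character(1))
  fam_b <- make_family(n_per, len, within,
                       diagnostics = list(c(as.character(diag_pos[1]), "H"),
                                          c(as.character(diag_pos[2]), "Q")),
                       seed = seed + 13, prefix = "B",
                       ancestor = paste(av, collapse = ""))
  list(a = fam_a, b = fam_b)
}

# deterministic search for a one-gene genome whose planted GC-AG intron
# admits no alternative canonical stitch: the intron body is G-free by
# construction, and the seed is advanced until the coding-strand exon tail
# next to the donor carries no GT either
make_gcag_case <- function(base_seed) {
  fam <- make_family(3, 240, 0.08, seed = base_seed, prefix = "NC")
  pep <- unclass(fam$seqs)[[3]]
  for (s in base_seed + seq(0, 400)) {
    gen <- make_genome(list(list(id = "nc", peptide = pep, n_exons = 2)),
                       intergenic_len = 800, intron_len_range = c(80, 200),
                       seed = s, noncanonical_for = "nc")
    tr <- gen$truth$nc
    g <- gen$genome[[1]]
    ex <- tr$exons
    # coding-order first exon and its 60-nt tail on the coding strand
    tail_seq <- if (tr$strand == "+") {
      substring(g, max(ex$start[1], ex$end[1] - 59), ex$end[1])
    } else {
      i <- nrow(ex)
      reverse_complement(substring(g, ex$start[i],
                                   min(ex$end[i], ex$start[i] + 59)))
    }
    if (!grepl("GT", tail_seq, fixed = TRUE)) {
      return(list(genome = gen$genome, truth = gen$truth,
                  bait_set = bait_set("NC", fam$seqs[1:2],
                                      names(fam$seqs)[1])))
    }
  }
  stop("no suitable non-canonical fixture found")
}
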