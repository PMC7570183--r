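test_that("alignments degap back to their inputs with both engines", {
  m <- build_msa(c(a = "ACDE", b = "ACE"), engine = "internal")
  expect_equal(nchar(m[[1]]), 4)            # one gap column
  expect_equal(gsub("-", "", m[["b"]]), "ACE")

  ident <- build_msa(c(x = "MKVL", y = "MKVL"), engine = "internal")
  expect_false(any(grepl("-", ident)))      # identical pair aligns gap-free

  set.seed(131)
  seqs <- stats::setNames(replicate(10, random_pep_str(sample(80:120, 1))),
                          paste0("s", 1:10))
  for (engine in c("internal", "mafft")) {
    m <- build_msa(seqs, engine = engine)
    expect_equal(length(unique(nchar(m))), 1)        # rectangular
    expect_identical(gsub("-", "", unclass(m)[names(seqs)]), seqs)
  }
})

test_that("occupancy filtering keeps exactly the columns above threshold", {
  rows <- c(r1 = "A-C", r2 = "A-C", r3 = "A--", r4 = "A-C", r5 = "A-C",
            r6 = "A-C", r7 = "A-C", r8 = "A-C", r9 = "A-C", r10 = "A-C",
            r11 = "A-C", r12 = "A-C", r13 = "A-C", r14 = "A-C", r15 = "A-C",
            r16 = "A-C", r17 = "A-C", r18 = "A-C", r19 = "A-C", r20 = "AGC")
  msa <- structure(rows, class = "msa")
  # column 2 has occupancy 1/20 = 0.05 < 0.1 -> removed
  out <- occupancy_filter(msa, 0.1)
  expect_equal(unname(unclass(out)[["r20"]]), "AC")
  expect_equal(unname(unclass(out)[["r1"]]), "AC")

  set.seed(141)
  for (i in 1:20) {
    nr <- sample(5:15, 1); nc <- sample(10:40, 1)
    mat <- matrix(sample(c(AA20, rep("-", 15)), nr * nc, replace = TRUE),
                  nrow = nr)
    msa <- structure(stats::setNames(apply(mat, 1, paste, collapse = ""),
                                     paste0("r", 1:nr)), class = "msa")
    keep_oracle <- which(colSums(mat != "-") / nr >= 0.1)
    got <- unclass(occupancy_filter(msa, 0.1))
    expect_identical(unname(got[["r1"]]),
                     paste(mat[1, keep_oracle], collapse = ""))
    # idempotence
    expect_identical(unclass(occupancy_filter(occupancy_filter(msa, 0.1), 0.1)),
                     got)
  }
})

test_that("a candidate identical to a bait sits at tree distance zero", {
  fam <- make_family(5, 150, 0.1, seed = 151, prefix = "T")
  bs <- bait_set("T", fam$seqs[1:4], names(fam$seqs)[1])
  cand <- stats::setNames(unclass(fam$seqs)[[2]], "copycat")
  asg <- classify_by_tree(cand, list(bs), msa_engine = "internal")
  expect_equal(asg$closest_bait_id, names(fam$seqs)[2])
  expect_equal(asg$value, 0, tolerance = 1e-9)
  expect_equal(asg$metric, "tree_distance")
})

test_that("tree classification separates two diagnostic-residue families", {
  pair <- make_family_pair(14, 250, seed = 161)
  a_ids <- names(pair$a$seqs); b_ids <- names(pair$b$seqs)
  bsA <- bait_set("famA", pair$a$seqs[1:4], a_ids[1])
  bsB <- bait_set("famB", pair$b$seqs[1:4], b_ids[1])
  cands <- c(stats::setNames(unclass(pair$a$seqs[5:14]),
                             paste0("ca", 1:10)),
             stats::setNames(unclass(pair$b$seqs[5:14]),
                             paste0("cb", 1:10)))
  asg <- classify_by_tree(cands, list(bsA, bsB))
  truth <- ifelse(grepl("^ca", asg$candidate_id), "famA", "famB")
  expect_identical(asg$reaction, truth)
})

test_that("small-instance tree assignment equals the pairwise-distance oracle", {
  set.seed(171)
  for (i in 1:8) {
    pair <- make_family_pair(3, 120, seed = 1700 + i)
    bsA <- bait_set("famA", pair$a$seqs[1:3], names(pair$a$seqs)[1])
    bsB <- bait_set("famB", pair$b$seqs[1:3], names(pair$b$seqs)[1])
    cand_seq <- if (i %% 2 == 0) unclass(pair$a$seqs)[[3]] else
      unclass(pair$b$seqs)[[3]]
    cand <- stats::setNames(cand_seq, "probe")
    baits <- c(unclass(bsA$baits), unclass(bsB$baits))
    # brute-force oracle: global pairwise alignment p-distance to every bait
    d <- vapply(baits, function(b) {
      pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(cand_seq),
                                          Biostrings::AAString(b),
                                          type = "global")
      1 - Biostrings::pid(pa, type = "PID1") / 100
    }, numeric(1))
    oracle_family <- if (names(which.min(d)) %in% names(bsA$baits)) "famA"
                     else "famB"
    asg <- classify_by_tree(cand, list(bsA, bsB), msa_engine = "internal")
    expect_equal(asg$reaction, oracle_family, info = paste("instance", i))
  }
})

test_that("similarity classification matches planted mixture provenance", {
  fam <- make_family(4, 200, 0.1, seed = 181, prefix = "M")
  pair <- make_family_pair(6, 200, seed = 182)
  bsA <- bait_set("famA", pair$a$seqs[1:4], names(pair$a$seqs)[1])
  bsB <- bait_set("famB", pair$b$seqs[1:4], names(pair$b$seqs)[1])
  # candidate built 80% from family A, 20% from family B
  a <- strsplit(unclass(pair$a$seqs)[[5]], "")[[1]]
  b <- strsplit(unclass(pair$b$seqs)[[5]], "")[[1]]
  chim <- a; chim[161:200] <- b[161:200]
  cand <- stats::setNames(paste(chim, collapse = ""), "chimera")
  asg <- classify_by_similarity(cand, list(bsA, bsB))
  expect_equal(asg$reaction, "famA")
  expect_equal(asg$metric, "alignment_similarity")
  expect_true(asg$value >= 0 && asg$value <= 1)

  exact <- classify_by_similarity(stats::setNames(unclass(bsB$baits)[[2]],
                                                  "same"),
                                  list(bsA, bsB))
  expect_equal(exact$value, 1)
  expect_equal(exact$reaction, "famB")
})

test_that("close co-candidate reactions are recorded alongside the winner", {
  pair <- make_family_pair(6, 220, seed = 191, within = 0.05, between = 0.12)
  bsA <- bait_set("F3pH", pair$a$seqs[1:5], names(pair$a$seqs)[1])
  bsB <- bait_set("F3p5pH", pair$b$seqs[1:5], names(pair$b$seqs)[1])
  cand <- stats::setNames(unclass(pair$b$seqs)[[6]], "cand")
  asg <- classify_by_tree(cand, list(bsA, bsB), k_nearest = 6)
  expect_equal(asg$reaction, "F3p5pH")
  expect_match(asg$co_candidates, "F3pH")
})

test_that("assignments are stable under candidate permutation", {
  pair <- make_family_pair(8, 180, seed = 201)
  bsA <- bait_set("famA", pair$a$seqs[1:4], names(pair$a$seqs)[1])
  bsB <- bait_set("famB", pair$b$seqs[1:4], names(pair$b$seqs)[1])
  cands <- c(stats::setNames(unclass(pair$a$seqs[5:8]), paste0("x", 1:4)),
             stats::setNames(unclass(pair$b$seqs[5:8]), paste0("y", 1:4)))
  a1 <- classify_by_tree(cands, list(bsA, bsB))
  a2 <- classify_by_tree(rev(cands), list(bsA, bsB))
  a1 <- a1[order(a1$candidate_id), ]; a2 <- a2[order(a2$candidate_id), ]
  expect_equal(a1$reaction, a2$reaction)
  expect_equal(a1$closest_bait_id, a2$closest_bait_id)
})
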