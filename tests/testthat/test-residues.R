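# small helper: msa object from aligned strings
msa_of <- function(...) structure(c(...), class = "msa")

test_that("reference positions map through gapped alignments", {
  m <- msa_of(ref = "MKVLQA", cand = "MKVLQA")
  mp <- map_positions(m, "ref", "cand", c(1, 5))
  expect_equal(mp$cand_position, c(1, 5))
  expect_equal(mp$observed, c("M", "Q"))

  # candidate insertion upstream shifts the mapped index
  m2 <- msa_of(ref = "MKV-----LQA", cand = "MKVTTTTTLQA")
  mp2 <- map_positions(m2, "ref", "cand", 4)   # L, reference position 4
  expect_equal(mp2$cand_position, 9)
  expect_equal(mp2$observed, "L")

  # gap in the candidate reports absent
  m3 <- msa_of(ref = "MKVLQA", cand = "MKV-QA")
  mp3 <- map_positions(m3, "ref", "cand", 4)
  expect_true(is.na(mp3$cand_position))
  expect_equal(mp3$observed, "-")

  expect_error(map_positions(m, "ref", "cand", 99), "beyond reference")
})

test_that("position mapping agrees with a brute-force column walk", {
  set.seed(211)
  for (i in 1:100) {
    len <- sample(20:60, 1)
    ref <- strsplit(random_pep_str(len), "")[[1]]
    cand <- strsplit(random_pep_str(len), "")[[1]]
    # inject random gap columns into both rows
    ncol <- len + sample(5:15, 1)
    ref_cols <- sort(sample(ncol, len)); cand_cols <- sort(sample(ncol, len))
    r <- rep("-", ncol); r[ref_cols] <- ref
    c_ <- rep("-", ncol); c_[cand_cols] <- cand
    m <- msa_of(ref = paste(r, collapse = ""), cand = paste(c_, collapse = ""))
    pos <- sample(len, 3)
    mp <- map_positions(m, "ref", "cand", pos)
    for (k in seq_along(pos)) {
      col <- ref_cols[pos[k]]                 # brute-force column walk
      expect_equal(mp$column[k], col)
      if (c_[col] == "-") {
        expect_true(is.na(mp$cand_position[k]))
      } else {
        expect_equal(mp$cand_position[k], sum(c_[1:col] != "-"))
        expect_equal(mp$observed[k], c_[col])
      }
    }
  }
})

chs_spec <- function() {
  structure(list(
    reaction = "CHS",
    residue_rules = data.frame(position = c(166, 167), allowed = c("Q", "Q"),
                               label = c("Q166", "Q167"),
                               stringsAsFactors = FALSE),
    domain_rules = data.frame(start = 10, end = 29, name = "motif",
                              min_identity = 0.6, stringsAsFactors = FALSE),
    specificity_rules = data.frame(position = integer(), residue = character(),
                                   annotation = character(),
                                   stringsAsFactors = FALSE)),
    class = "reference_spec")
}

test_that("residue checks distinguish match, mismatch and similar", {
  fam <- make_family(3, 300, 0.05,
                     diagnostics = list(c("166", "Q"), c("167", "Q")),
                     seed = 221, prefix = "C")
  ref <- unclass(fam$seqs)[[1]]
  good <- stats::setNames(unclass(fam$seqs)[[2]], "good")
  bad <- stats::setNames(make_mutant(good, list(c("167", "H"))), "bad")
  m <- build_msa(c(ref = ref, good = unname(good), bad = unname(bad)),
                 engine = "internal")
  spec <- chs_spec()
  rc_good <- check_residues(m, spec, "good", "ref")
  expect_true(all(rc_good$status == "match"))
  rc_bad <- check_residues(m, spec, "bad", "ref")
  expect_equal(rc_bad$status, c("match", "mismatch"))
  expect_equal(rc_bad$observed[2], "H")

  # K where R is allowed counts as similar only in similar mode
  spec2 <- chs_spec(); spec2$residue_rules$allowed <- c("R", "Q")
  kmut <- stats::setNames(make_mutant(good, list(c("166", "K"))), "kmut")
  m2 <- build_msa(c(ref = ref, kmut = unname(kmut)), engine = "internal")
  expect_equal(check_residues(m2, spec2, "kmut", "ref")$status[1], "mismatch")
  expect_equal(check_residues(m2, spec2, "kmut", "ref",
                              similar_mode = TRUE)$status[1], "similar")
})

test_that("domain conservation is column identity over the reference span", {
  ref <- random_pep_str(60)
  same <- stats::setNames(ref, "same")
  m <- msa_of(ref = ref, same = ref)
  spec <- chs_spec()
  dc <- check_domains(m, spec, "same", "ref")
  expect_equal(dc$identity, 1.0)
  expect_true(dc$conserved)

  gap <- paste0(substring(ref, 1, 5), strrep("-", 25), substring(ref, 31))
  m2 <- msa_of(ref = ref, gapped = gap)
  dc2 <- check_domains(m2, spec, "gapped", "ref")
  expect_equal(dc2$identity, 0.0)
  expect_false(dc2$conserved)

  # randomized span, identity equals a hand count
  set.seed(231)
  v <- strsplit(ref, "")[[1]]
  idx <- sample(10:29, 8)
  v[idx] <- vapply(v[idx], function(x) sample(setdiff(AA20, x), 1), "")
  rnd <- paste(v, collapse = "")
  m3 <- msa_of(ref = ref, rnd = rnd)
  hand <- mean(strsplit(ref, "")[[1]][10:29] == v[10:29])
  expect_equal(check_domains(m3, spec, "rnd", "ref")$identity, hand,
               tolerance = 1e-9)
})

test_that("functionality requires a match at all checked positions", {
  rc <- data.frame(label = c("a", "b"), ref_position = c(1, 2),
                   cand_position = c(1, 2), allowed = c("Q", "Q"),
                   observed = c("Q", "Q"), status = c("match", "match"),
                   stringsAsFactors = FALSE)
  dc <- data.frame(name = "m", start = 1, end = 5, identity = 0.9,
                   min_identity = 0.6, conserved = TRUE,
                   stringsAsFactors = FALSE)
  call <- predict_functionality("c", "CHS", rc, dc)
  expect_equal(call$prediction, "functional")

  rc2 <- rc; rc2$status[2] <- "mismatch"; rc2$observed[2] <- "H"
  call2 <- predict_functionality("c", "CHS", rc2, dc)
  expect_equal(call2$prediction, "possibly_nonfunctional")
  expect_match(call2$violations[1], "b")

  # monotone: adding a rule can only keep or revoke functional
  call3 <- predict_functionality("c", "CHS", rbind(rc, rc2[2, ]), dc)
  expect_equal(call3$prediction, "possibly_nonfunctional")
  # zero rules: vacuously functional with a caveat
  call4 <- predict_functionality("c", "CHS", rc[0, ], dc[0, ])
  expect_equal(call4$prediction, "functional")
  expect_match(call4$notes[1], "no residue or domain rules")
})

test_that("contrasting residues recover planted columns and nothing else", {
  set.seed(241)
  fam_a <- make_family(10, 150, 0.08,
                       diagnostics = list(c("70", "Q"), c("71", "Q")),
                       seed = 242, prefix = "qa")
  fam_b <- make_family(10, 150, 0.08,
                       diagnostics = list(c("70", "Q"), c("71", "H")),
                       seed = 242, prefix = "qb")
  cr <- contrasting_residues(unclass(fam_a$seqs), unclass(fam_b$seqs),
                             purity = 0.9, msa_engine = "internal")
  expect_equal(cr$position, 71)
  expect_equal(cr$residues_a, "Q")
  expect_equal(cr$residues_b, "H")

  # identical sets contrast nowhere
  same <- contrasting_residues(unclass(fam_a$seqs), unclass(fam_a$seqs),
                               purity = 0.9, msa_engine = "internal")
  expect_equal(nrow(same), 0)
})

test_that("one noisy row hides a contrast at purity 1.0 but not at 0.9", {
  fam_a <- make_family(10, 120, 0, diagnostics = list(c("60", "Q")),
                       seed = 251, prefix = "na")
  fam_b <- make_family(10, 120, 0, diagnostics = list(c("60", "H")),
                       seed = 251, prefix = "nb")
  noisy <- unclass(fam_a$seqs)
  noisy[[1]] <- make_mutant(noisy[[1]], list(c("60", "H")))
  strict <- contrasting_residues(noisy, unclass(fam_b$seqs), purity = 1.0,
                                 msa_engine = "internal")
  expect_false(60 %in% strict$position)
  relaxed <- contrasting_residues(noisy, unclass(fam_b$seqs), purity = 0.9,
                                  msa_engine = "internal")
  expect_true(60 %in% relaxed$position)
})

test_that("substrate-specificity notes follow the observed residue", {
  kb <- load_knowledge_base(system.file("extdata", "flavonoid_synthetic",
                                        "config.txt", package = "pathenz"))
  bs <- kb$DFR$bait_set; spec <- kb$DFR$spec
  ref <- reference_seq <- bs$baits[[bs$reference_id]]
  expects <- c(N = "dihydroquercetin", D = "reduced dihydrokaempferol",
               L = "dihydrokaempferol preference", A = "dihydrokaempferol preference")
  for (aa in names(expects)) {
    cand <- make_mutant(stats::setNames(ref, "cand"),
                        list(c("133", aa)))
    m <- build_msa(c(stats::setNames(ref, bs$reference_id), cand = unname(cand)),
                   engine = "internal")
    call <- predict_functionality("cand", "DFR",
                                  check_residues(m, spec, "cand",
                                                 bs$reference_id),
                                  check_domains(m, spec, "cand",
                                                bs$reference_id))
    before <- call$prediction
    call <- annotate_specificity(call, spec, m, bs$reference_id)
    expect_equal(call$prediction, before)   # notes never change the call
    expect_true(any(grepl(expects[[aa]], call$notes)), info = aa)
  }
})
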