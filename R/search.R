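#' Scoring scheme for protein local alignment
#'
#' @param matrix substitution matrix name shipped with Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open gap opening penalty (default 11).
#' @param gap_ext gap extension penalty (default 1).
#' @return list with the resolved substitution matrix and gap penalties.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_ext = 1) {
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  structure(list(name = matrix, mat = get(matrix, envir = e),
                 gap_open = gap_open, gap_ext = gap_ext),
            class = "scoring_scheme")
}

#' Score of a peptide aligned gap-free against itself
#'
#' The denominator of the score-ratio filter: the sum over residues of the
#' substitution-matrix diagonal.
#'
#' @param seq peptide string.
#' @param scoring a [scoring_scheme()].
#' @return numeric self-alignment score.
#' @export
self_score <- function(seq, scoring = scoring_scheme()) {
  s <- toupper(as.character(seq)[[1]])
  if (!nzchar(s)) stop("empty sequence has no self-score")
  aa <- strsplit(s, "")[[1]]
  sum(diag(scoring$mat)[aa])
}

empty_hits <- function() {
  structure(data.frame(
    query_id = character(), subject_id = character(), identity = numeric(),
    score = numeric(), self_score = numeric(),
    q_start = integer(), q_end = integer(), s_start = integer(), s_end = integer(),
    strand = character(), frame = integer(), mode = character(),
    stringsAsFactors = FALSE),
    class = c("search_hits", "data.frame"))
}

as_hits <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(empty_hits())
  class(df) <- c("search_hits", "data.frame")
  rownames(df) <- NULL
  df
}

# split one pairwise local alignment into segments at long gaps in the bait
# row (insertions in the subject, e.g. a stop-free in-frame intron bridged by
# the aligner); returns per-segment coords/score/identity
split_alignment_segments <- function(p_aln, s_aln, p_start, s_start, scoring,
                                     split_gap_aa) {
  p <- strsplit(p_aln, "")[[1]]
  s <- strsplit(s_aln, "")[[1]]
  r <- rle(s == "-")
  ends <- cumsum(r$lengths)
  long <- which(r$values & r$lengths >= split_gap_aa)
  seg_bounds <- rbind(c(1, length(s)))
  if (length(long)) {
    cutpoints <- cbind(ends[long] - r$lengths[long] + 1, ends[long])
    starts <- c(1, cutpoints[, 2] + 1)
    stops <- c(cutpoints[, 1] - 1, length(s))
    seg_bounds <- cbind(starts, stops)
  }
  p_pos <- cumsum(p != "-") + p_start - 1L
  s_pos <- cumsum(s != "-") + s_start - 1L
  out <- list()
  for (i in seq_len(nrow(seg_bounds))) {
    cols <- seg_bounds[i, 1]:seg_bounds[i, 2]
    cols <- cols[p[cols] != "-" | s[cols] != "-"]
    keep <- cols[p[cols] != "-" & s[cols] != "-"]
    if (length(keep) == 0) next
    cols <- min(keep):max(keep)
    match_cols <- p[cols] != "-" & s[cols] != "-"
    sc <- sum(scoring$mat[cbind(p[cols][match_cols], s[cols][match_cols])])
    gap_runs <- rle(!match_cols)
    n_gap_runs <- sum(gap_runs$values)
    sc <- sc - n_gap_runs * scoring$gap_open -
      sum(gap_runs$lengths[gap_runs$values]) * scoring$gap_ext
    out[[length(out) + 1L]] <- data.frame(
      score = sc,
      identity = mean(p[cols] == s[cols]),
      p_start = min(p_pos[cols][p[cols] != "-"]),
      p_end = max(p_pos[cols][p[cols] != "-"]),
      s_start = min(s_pos[cols][s[cols] != "-"]),
      s_end = max(s_pos[cols][s[cols] != "-"]))
  }
  do.call(rbind, out)
}

# one local alignment of bait (query) vs a set of subject peptides;
# returns a hit data.frame (no frame/strand annotation). With split_gap_aa
# set, hits are split at bait-side gaps of at least that many residues.
align_bait_vs_peptides <- function(bait_id, bait, subjects, scoring,
                                   min_score = 1, split_gap_aa = NULL) {
  subj_set <- Biostrings::AAStringSet(unlist(subjects))
  names(subj_set) <- names(subjects)
  if (length(subj_set) > 50) {
    # cheap score-only pass so detailed alignment runs only on candidates
    sc0 <- Biostrings::pairwiseAlignment(
      pattern = subj_set, subject = Biostrings::AAString(bait),
      type = "local", substitutionMatrix = scoring$mat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext,
      scoreOnly = TRUE)
    subj_set <- subj_set[sc0 >= min_score]
    if (length(subj_set) == 0) return(empty_hits())
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = subj_set, subject = Biostrings::AAString(bait),
    type = "local", substitutionMatrix = scoring$mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
  sc <- Biostrings::score(pa)
  keep <- which(sc >= min_score)
  if (length(keep) == 0) return(empty_hits())
  pid <- Biostrings::pid(pa[keep], type = "PID1") / 100
  pat <- pa[keep]@pattern
  subj <- pa[keep]@subject
  hits <- as_hits(data.frame(
    query_id = bait_id,
    subject_id = names(subj_set)[keep],
    identity = pid,
    score = sc[keep],
    self_score = self_score(bait, scoring),
    q_start = IRanges::start(subj@range), q_end = IRanges::end(subj@range),
    s_start = IRanges::start(pat@range), s_end = IRanges::end(pat@range),
    strand = "+", frame = NA_integer_, mode = "pep", stringsAsFactors = FALSE))
  if (is.null(split_gap_aa)) return(hits)
  p_alns <- as.character(Biostrings::alignedPattern(pa[keep]))
  s_alns <- as.character(Biostrings::alignedSubject(pa[keep]))
  out <- list()
  for (i in seq_len(nrow(hits))) {
    segs <- split_alignment_segments(p_alns[i], s_alns[i], hits$s_start[i],
                                     hits$q_start[i], scoring, split_gap_aa)
    if (is.null(segs) || nrow(segs) == 1) {
      out[[length(out) + 1L]] <- hits[i, , drop = FALSE]
      next
    }
    segs <- segs[segs$score >= min_score, , drop = FALSE]
    if (nrow(segs) == 0) next
    h <- hits[rep(i, nrow(segs)), , drop = FALSE]
    h$score <- segs$score
    h$identity <- segs$identity
    h$q_start <- segs$s_start; h$q_end <- segs$s_end
    h$s_start <- segs$p_start; h$s_end <- segs$p_end
    out[[length(out) + 1L]] <- h
  }
  as_hits(do.call(rbind, out))
}

# repeated masked local alignment so that several non-overlapping hits per
# subject (e.g. one per exon) are recovered
align_bait_vs_peptides_multi <- function(bait_id, bait, subjects, scoring,
                                         min_score = 40, max_hits = 8) {
  first <- align_bait_vs_peptides(bait_id, bait, subjects, scoring,
                                  min_score = min_score)
  if (nrow(first) == 0) return(first)
  out <- list()
  for (sid in unique(first$subject_id)) {
    s <- subjects[[sid]]
    for (i in seq_len(max_hits)) {
      h <- align_bait_vs_peptides(bait_id, bait, stats::setNames(list(s), sid),
                                  scoring, min_score = min_score,
                                  split_gap_aa = 15)
      if (nrow(h) == 0) break
      out[[length(out) + 1L]] <- h
      # mask the matched subject span(s) and look for further hits
      sv <- strsplit(s, "")[[1]]
      for (k in seq_len(nrow(h))) sv[h$s_start[k]:h$s_end[k]] <- "X"
      s <- paste(sv, collapse = "")
    }
  }
  as_hits(do.call(rbind, out))
}

#' Search subject sequences for similarity to a reaction's baits
#'
#' Peptide subjects are aligned locally against every bait; transcript
#' subjects are first expanded into six-frame stop-free peptide fragments;
#' genome subjects are expanded the same way and hits are reported in
#' forward-strand genomic coordinates with strand and frame, so that they can
#' be grouped into loci and stitched into gene models. Every hit carries its
#' bait's self-alignment score.
#'
#' @param baits a [bait_set()].
#' @param subjects a [seqset()] (peptide for `pep`, dna for `rna`/`dna`).
#' @param mode `"pep"`, `"rna"` or `"dna"`.
#' @param scoring a [scoring_scheme()].
#' @param min_fragment_len minimum six-frame fragment length in residues for
#'   `rna` mode (default 50).
#' @param min_exon_score raw-score floor for translated genome hits
#'   (default 40); suppresses spurious short local matches.
#' @param engine `"internal"` (Smith–Waterman via Biostrings) or `"blast"`
#'   (external BLAST+ binaries, which must be on the PATH).
#' @return a `search_hits` data.frame: `query_id, subject_id, identity,
#'   score, self_score, q_start, q_end, s_start, s_end, strand, frame`.
#'   For `dna` mode `s_start`/`s_end` are genomic forward-strand coordinates;
#'   for `rna` mode `subject_id` is the transcript id and coordinates refer
#'   to the translated fragment, with `frame` recorded.
#' @export
search_candidates <- function(baits, subjects, mode = c("pep", "rna", "dna"),
                              scoring = scoring_scheme(),
                              min_fragment_len = 50, min_exon_score = 40,
                              engine = c("internal", "blast")) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  if (mode == "pep" && seq_kind(subjects) != "peptide") {
    stop("pep mode requires peptide subjects")
  }
  if (mode %in% c("rna", "dna") && seq_kind(subjects) != "dna") {
    stop(mode, " mode requires nucleotide subjects")
  }
  if (engine == "blast") return(blast_search(baits, subjects, mode, scoring))
  bait_list <- as.list(unclass(baits$baits))
  if (mode == "pep") {
    subj <- as.list(unclass(subjects))
    hits <- as_hits(do.call(rbind, lapply(names(bait_list), function(b)
      align_bait_vs_peptides(b, bait_list[[b]], subj, scoring))))
    if (nrow(hits)) hits$mode <- "pep"
    return(hits)
  }
  # translate
  frag_min <- if (mode == "rna") min_fragment_len else 10
  frag_tab <- do.call(rbind, lapply(names(subjects), function(id)
    six_frame_fragments(subjects[[id]], min_fragment_len = frag_min,
                        parent_id = id)))
  if (is.null(frag_tab) || nrow(frag_tab) == 0) return(empty_hits())
  frag_ids <- sprintf("%s|f%+d|%d", frag_tab$parent_id, frag_tab$frame,
                      frag_tab$start_nt)
  frags <- stats::setNames(as.list(frag_tab$residues), frag_ids)
  hits <- lapply(names(bait_list), function(b) {
    if (mode == "rna") {
      align_bait_vs_peptides(b, bait_list[[b]], frags, scoring)
    } else {
      align_bait_vs_peptides_multi(b, bait_list[[b]], frags, scoring,
                                   min_score = min_exon_score)
    }
  })
  hits <- as_hits(do.call(rbind, hits))
  if (nrow(hits) == 0) return(hits)
  idx <- match(hits$subject_id, frag_ids)
  hits$frame <- frag_tab$frame[idx]
  hits$strand <- ifelse(hits$frame > 0, "+", "-")
  parent <- frag_tab$parent_id[idx]
  if (mode == "dna") {
    # fragment-local aa coordinates -> genomic forward-strand nt coordinates
    start_nt <- frag_tab$start_nt[idx]
    len_aa <- nchar(frag_tab$residues[idx])
    fwd <- hits$frame > 0
    g_start <- ifelse(fwd, start_nt + 3L * (hits$s_start - 1L),
                      start_nt + 3L * (len_aa - hits$s_end))
    g_end <- ifelse(fwd, start_nt + 3L * hits$s_end - 1L,
                    start_nt + 3L * (len_aa - hits$s_start + 1L) - 1L)
    hits$s_start <- as.integer(g_start)
    hits$s_end <- as.integer(g_end)
    hits$subject_id <- parent
  }
  hits$mode <- mode
  hits
}

#' Apply the dual candidate filter to search hits
#'
#' Retains exactly the hits whose identity exceeds `min_identity` and whose
#' score exceeds `min_score_ratio` of the bait's self-alignment score. Both
#' comparisons are strict, and the input order is preserved. The defaults
#' are the lenient screening thresholds used to collect a comprehensive
#' candidate set before alignment- and tree-based refinement.
#'
#' @param hits a `search_hits` data.frame.
#' @param min_identity identity threshold in `[0,1]` (default 0.40).
#' @param min_score_ratio self-score-ratio threshold in `[0,1]` (default 0.30).
#' @return the retained hits.
#' @export
filter_hits <- function(hits, min_identity = 0.40, min_score_ratio = 0.30) {
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_score_ratio >= 0, min_score_ratio <= 1)
  if (nrow(hits) == 0) return(hits)
  keep <- hits$identity > min_identity &
    hits$score / hits$self_score > min_score_ratio
  as_hits(hits[keep, , drop = FALSE])
}

#' Write / read search hits as outfmt-6-style TSV
#'
#' Column order `qseqid sseqid pident length qstart qend sstart send score
#' selfscore strand frame`, identities as percentages, for interchange with
#' external alignment tools.
#'
#' @param hits a `search_hits` data.frame.
#' @param path TSV file.
#' @return `write_hits_tsv`: the path, invisibly. `read_hits_tsv`: hits.
#' @export
write_hits_tsv <- function(hits, path) {
  df <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = round(hits$identity * 100, 2),
    length = abs(hits$q_end - hits$q_start) + 1L,
    qstart = hits$q_start, qend = hits$q_end,
    sstart = hits$s_start, send = hits$s_end,
    score = hits$score, selfscore = hits$self_score,
    strand = hits$strand, frame = hits$frame, mode = hits$mode)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_hits(data.frame(
    query_id = df$qseqid, subject_id = df$sseqid, identity = df$pident / 100,
    score = df$score, self_score = df$selfscore,
    q_start = df$qstart, q_end = df$qend, s_start = df$sstart, s_end = df$send,
    strand = df$strand, frame = df$frame, mode = df$mode,
    stringsAsFactors = FALSE))
}

# external BLAST+ engine: blastp for peptide subjects, tblastn for nucleotide
blast_search <- function(baits, subjects, mode, scoring) {
  prog <- if (mode == "pep") "blastp" else "tblastn"
  for (bin in c(prog, "makeblastdb")) {
    if (!nzchar(Sys.which(bin))) stop("external search engine requested but '",
                                      bin, "' is not on the PATH")
  }
  td <- tempfile("blast"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  qf <- file.path(td, "query.fa"); sf <- file.path(td, "db.fa")
  write_fasta(baits$baits, qf)
  write_fasta(subjects, sf)
  dbtype <- if (mode == "pep") "prot" else "nucl"
  system2("makeblastdb", c("-in", sf, "-dbtype", dbtype, "-out",
                           file.path(td, "db")), stdout = FALSE, stderr = FALSE)
  out <- file.path(td, "hits.tsv")
  fmt <- "6 qseqid sseqid pident length qstart qend sstart send score"
  system2(prog, c("-query", qf, "-db", file.path(td, "db"), "-outfmt",
                  shQuote(fmt), "-out", out, "-evalue", "1e-3"),
          stdout = FALSE, stderr = FALSE)
  df <- tryCatch(utils::read.delim(out, header = FALSE,
                                   stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0) return(empty_hits())
  names(df) <- c("qseqid", "sseqid", "pident", "length", "qstart", "qend",
                 "sstart", "send", "score")
  minus <- df$sstart > df$send
  selfs <- vapply(as.list(unclass(baits$baits)), self_score, numeric(1),
                  scoring = scoring)
  as_hits(data.frame(
    query_id = df$qseqid, subject_id = df$sseqid, identity = df$pident / 100,
    score = df$score, self_score = unname(selfs[df$qseqid]),
    q_start = df$qstart, q_end = df$qend,
    s_start = pmin(df$sstart, df$send), s_end = pmax(df$sstart, df$send),
    strand = ifelse(mode == "pep", "+", ifelse(minus, "-", "+")),
    frame = NA_integer_, mode = mode, stringsAsFactors = FALSE))
}
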