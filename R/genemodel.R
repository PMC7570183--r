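#' Group translated genome hits into candidate loci
#'
#' Hits of one bait on the same contig and strand are chained left to right
#' when the genomic gap between consecutive hits does not exceed
#' `max_intron_len`, the hits do not overlap genomically, and their bait
#' coordinates advance colinearly with genomic order (strand-aware). Each
#' chain is one candidate locus from which a single isoform is later
#' constructed.
#'
#' @param hits `search_hits` from a `dna`-mode search.
#' @param max_intron_len maximum allowed intron length in nt (default 20000).
#' @param max_overlap_aa tolerated bait-coordinate overlap between
#'   consecutive exon hits, in residues (default 30; local alignment can
#'   overshoot an exon edge considerably when the intron's in-frame
#'   translation resembles the bait).
#' @return list of `locus` objects (`contig`, `strand`, `query_id`,
#'   `fragments` sorted by genomic start).
#' @export
group_hits <- function(hits, max_intron_len = 20000, max_overlap_aa = 30) {
  if (nrow(hits) > 0 && any(hits$mode != "dna")) {
    stop("group_hits expects dna-mode hits")
  }
  loci <- list()
  if (nrow(hits) == 0) return(loci)
  hits <- unique(hits)
  keys <- interaction(hits$query_id, hits$subject_id, hits$strand, drop = TRUE)
  for (k in levels(keys)) {
    h <- hits[keys == k, , drop = FALSE]
    h <- h[order(h$s_start), , drop = FALSE]
    cur <- h[1, , drop = FALSE]
    flush <- function(cur) {
      loci[[length(loci) + 1L]] <<- structure(
        list(contig = cur$subject_id[1], strand = cur$strand[1],
             query_id = cur$query_id[1], fragments = cur),
        class = "locus")
    }
    if (nrow(h) > 1) {
      for (i in 2:nrow(h)) {
        prev <- cur[nrow(cur), ]
        gap <- h$s_start[i] - prev$s_end - 1L
        colinear <- if (prev$strand == "+") {
          h$q_start[i] >= prev$q_end - max_overlap_aa
        } else {
          h$q_end[i] <= prev$q_start + max_overlap_aa
        }
        if (gap >= 1 && gap <= max_intron_len && colinear) {
          cur <- rbind(cur, h[i, , drop = FALSE])
        } else {
          flush(cur)
          cur <- h[i, , drop = FALSE]
        }
      }
    }
    flush(cur)
  }
  loci
}

#' @export
print.locus <- function(x, ...) {
  cat("<locus>", x$contig, x$strand, "| bait", x$query_id, "|",
      nrow(x$fragments), "fragment(s)\n")
  invisible(x)
}

# candidate splice boundaries around one junction on the coding strand:
# donor d (last exon base, intron starts GT at d+1) and acceptor a (first
# base of the next exon, intron ends AG at a-1), frame-preserving per junction
junction_candidates <- function(g, e_end, s_next, cs_left, ce_right,
                                window_d, window_a = window_d) {
  dr <- max(cs_left + 1, e_end - window_d):min(nchar(g) - 2, e_end + window_d)
  dr <- dr[substring(g, dr + 1, dr + 2) == "GT"]
  ar <- max(3, s_next - window_a):min(ce_right - 1, s_next + window_a)
  ar <- ar[substring(g, ar - 2, ar - 1) == "AG"]
  if (length(dr) == 0 || length(ar) == 0) return(NULL)
  combos <- expand.grid(d = dr, a = ar)
  combos <- combos[combos$a - combos$d - 1 >= 4, , drop = FALSE]
  ok <- ((combos$d - e_end) - (combos$a - s_next)) %% 3 == 0
  combos <- combos[ok, , drop = FALSE]
  if (nrow(combos) == 0) return(NULL)
  combos$shift <- abs(combos$d - e_end) + abs(combos$a - s_next)
  combos
}

# local spliced peptide across a junction; lc/right_end fix the outer
# genomic span so every candidate boundary pair is scored over the same
# region and differences reflect only the junction placement
junction_peptide <- function(g, cs_left, d, a, ce_right, lc, right_end) {
  nt <- paste0(substring(g, lc, d), substring(g, a, right_end))
  nt <- substring(nt, 1, (nchar(nt) %/% 3) * 3)
  if (!nzchar(nt)) return("")
  translate_frame(nt, 1L)
}

#' Stitch one isoform from a locus of exon hits
#'
#' Exon boundaries are shifted by at most `search_window` nt from the raw hit
#' edges so that every intron starts `GT` and ends `AG` on the coding strand
#' and the spliced coding sequence stays in frame with no internal stop.
#' Among feasible boundary pairs at a junction, the one whose junction-local
#' spliced peptide scores highest against the bait is chosen (ties: smallest
#' total shift, then leftmost donor). When no canonical, stop-free stitching
#' exists, the locus is demoted to its single best fragment and flagged
#' `"non-canonical-or-partial"` rather than dropped.
#'
#' @param locus a `locus` from [group_hits()].
#' @param genome dna [seqset()] containing the locus contig.
#' @param search_window maximum boundary shift in nt (default 30).
#' @param bait the bait peptide used for junction scoring (default: looked up
#'   by `locus$query_id` is not possible here, so pass it; `NULL` falls back
#'   to smallest-shift selection only).
#' @param scoring a [scoring_scheme()].
#' @return a `gene_model`: `contig, strand, query_id, exons, introns`
#'   (forward-strand coordinate data.frames), `cds`, `peptide`, `score`,
#'   `status` (`"complete"` or `"non-canonical-or-partial"`).
#' @export
stitch_isoform <- function(locus, genome, search_window = 30, bait = NULL,
                           scoring = scoring_scheme()) {
  contig <- genome[[locus$contig]]
  L <- nchar(contig)
  minus <- locus$strand == "-"
  g <- if (minus) reverse_complement(contig) else contig
  fr <- locus$fragments
  # coding-strand coordinates, ascending
  if (minus) {
    cs <- L - fr$s_end + 1L; ce <- L - fr$s_start + 1L
  } else {
    cs <- fr$s_start; ce <- fr$s_end
  }
  o <- order(cs)
  cs <- cs[o]; ce <- ce[o]
  frag_scores <- fr$score[o]
  # bait coordinates follow coding order on both strands after the transform
  qs <- fr$q_start[o]; qe <- fr$q_end[o]
  n <- length(cs)

  demote <- function() {
    b <- which.max(frag_scores)
    build_model(locus, g, L, minus, cs[b], ce[b],
                status = "non-canonical-or-partial", scoring = scoring,
                bait = bait, q_first = qs[b], q_last = qe[b])
  }
  if (n == 1) {
    return(build_model(locus, g, L, minus, cs, ce, status = "complete",
                       scoring = scoring, bait = bait, q_first = qs[1],
                       q_last = qe[1]))
  }

  # rank candidate boundary pairs per junction
  per_junction <- vector("list", n - 1)
  for (j in seq_len(n - 1)) {
    # when adjacent hits cover overlapping bait residues the aligner has
    # extended one or both edges across the intron; widen the boundary
    # search by the overlap so the true splice sites stay reachable
    overlap_aa <- max(0L, qe[j] - qs[j + 1] + 1L)
    win <- search_window + 3L * overlap_aa
    combos <- junction_candidates(g, ce[j], cs[j + 1], cs[j], ce[j + 1], win)
    if (is.null(combos)) return(demote())
    if (!is.null(bait)) {
      lc <- cs[j] + 3 * max(0, (min(combos$d) - cs[j] + 1 - 45) %/% 3)
      right_end <- min(ce[j + 1], max(combos$a) + 44)
      combos$jscore <- vapply(seq_len(nrow(combos)), function(i) {
        pep <- junction_peptide(g, cs[j], combos$d[i], combos$a[i], ce[j + 1],
                                lc, right_end)
        if (!nzchar(pep)) return(-Inf)
        Biostrings::pairwiseAlignment(
          pattern = Biostrings::AAString(pep),
          subject = Biostrings::AAString(bait), type = "local",
          substitutionMatrix = scoring$mat, gapOpening = scoring$gap_open,
          gapExtension = scoring$gap_ext, scoreOnly = TRUE)
      }, numeric(1))
    } else {
      combos$jscore <- 0
    }
    combos <- combos[order(-combos$jscore, combos$shift, combos$d), ,
                     drop = FALSE]
    per_junction[[j]] <- combos
  }

  # assemble; on an internal stop, advance the offending junction's choice
  choice <- rep(1L, n - 1)
  for (attempt in 1:50) {
    ncs <- cs; nce <- ce
    for (j in seq_len(n - 1)) {
      nce[j] <- per_junction[[j]]$d[choice[j]]
      ncs[j + 1] <- per_junction[[j]]$a[choice[j]]
    }
    if (all(nce >= ncs)) {
      cds <- paste(substring(g, ncs, nce), collapse = "")
      if (nchar(cds) %% 3 == 0) {
        pep <- translate_frame(cds, 1L)
        if (!grepl("*", pep, fixed = TRUE)) {
          return(build_model(locus, g, L, minus, ncs, nce,
                             status = "complete", scoring = scoring,
                             bait = bait, q_first = qs[1], q_last = qe[n]))
        }
        # find the junction whose intron-proximal codon went bad: advance the
        # first junction that still has alternatives
      }
    }
    advanced <- FALSE
    for (j in seq_len(n - 1)) {
      if (choice[j] < nrow(per_junction[[j]])) {
        choice[j] <- choice[j] + 1L
        if (j > 1) choice[seq_len(j - 1)] <- 1L
        advanced <- TRUE
        break
      }
    }
    if (!advanced) break
  }
  demote()
}

# largest k <= want such that the k codons preceding pos (left) or following
# pos (right) on the coding strand are stop-free
stop_free_extension <- function(g, pos, want, side) {
  while (want > 0) {
    codstarts <- if (side == "left") pos - 3 * seq_len(want)
                 else pos + 3 * (seq_len(want) - 1) + 1
    if (all(codstarts >= 1) && max(codstarts) + 2 <= nchar(g)) {
      aa <- translate_frame(paste(substring(g, sort(codstarts),
                                            sort(codstarts) + 2),
                                  collapse = ""), 1L)
      if (!grepl("*", aa, fixed = TRUE)) return(want)
    }
    want <- want - 1
  }
  0L
}

# construct a gene_model from coding-strand exon coordinates; terminal exons
# are extended codon-wise toward full bait coverage unless a stop intervenes
build_model <- function(locus, g, L, minus, cs, ce, status, scoring,
                        bait = NULL, q_first = NULL, q_last = NULL) {
  o <- order(cs)
  cs <- cs[o]; ce <- ce[o]
  if (!is.null(bait) && !is.null(q_first)) {
    k <- stop_free_extension(g, cs[1], min(q_first - 1, (cs[1] - 1) %/% 3),
                             "left")
    cs[1] <- cs[1] - 3L * k
    n <- length(ce)
    kr <- stop_free_extension(g, ce[n],
                              min(nchar(bait) - q_last,
                                  (nchar(g) - ce[n]) %/% 3), "right")
    ce[n] <- ce[n] + 3L * kr
  }
  cds <- paste(substring(g, cs, ce), collapse = "")
  pep <- if (nchar(cds) %% 3 == 0) translate_frame(cds, 1L) else ""
  n <- length(cs)
  introns_c <- if (n > 1) data.frame(start = ce[-n] + 1L, end = cs[-1] - 1L)
               else data.frame(start = integer(), end = integer())
  back <- function(df) {
    if (nrow(df) == 0 || !minus) return(df)
    out <- data.frame(start = L - df$end + 1L, end = L - df$start + 1L)
    out[order(out$start), , drop = FALSE]
  }
  exons <- back(data.frame(start = cs, end = ce))
  introns <- back(introns_c)
  score <- if (!is.null(bait) && nzchar(pep) && !grepl("*", pep, fixed = TRUE)) {
    Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(pep), subject = Biostrings::AAString(bait),
      type = "local", substitutionMatrix = scoring$mat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext,
      scoreOnly = TRUE)
  } else sum(locus$fragments$score)
  # self-score-normalized score puts models built from different baits on a
  # comparable scale (used when competing models of one region are resolved)
  score_ratio <- if (!is.null(bait)) score / self_score(bait, scoring) else NA_real_
  structure(list(contig = locus$contig, strand = locus$strand,
                 query_id = locus$query_id, exons = exons, introns = introns,
                 cds = cds, peptide = sub("\\*$", "", pep), score = score,
                 score_ratio = score_ratio, status = status),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model>", x$contig, x$strand, "|", nrow(x$exons), "exon(s) |",
      x$status, "| bait", x$query_id, "\n")
  invisible(x)
}

#' Write gene models to GFF3
#'
#' Emits `gene`, `mRNA` and `CDS` features (1-based inclusive coordinates,
#' CDS phase computed in transcription order).
#'
#' @param models list of `gene_model` objects.
#' @param path output GFF3 file.
#' @param source value of the GFF3 source column (default `"pathenz"`).
#' @return the path, invisibly.
#' @export
write_gff3 <- function(models, path, source = "pathenz") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_along(models)) {
    m <- models[[i]]
    id <- sprintf("gene%04d", i)
    gs <- min(m$exons$start); ge <- max(m$exons$end)
    row <- function(type, s, e, phase, attrs) {
      paste(m$contig, source, type, s, e, format(round(m$score, 1)),
            m$strand, phase, attrs, sep = "\t")
    }
    writeLines(row("gene", gs, ge, ".", paste0("ID=", id, ";status=", m$status,
                                               ";bait=", m$query_id)), con)
    writeLines(row("mRNA", gs, ge, ".", paste0("ID=", id, ".t1;Parent=", id)),
               con)
    ex <- m$exons
    ord <- if (m$strand == "-") order(-ex$start) else order(ex$start)
    cum <- 0L
    for (k in ord) {
      phase <- (3L - (cum %% 3L)) %% 3L
      writeLines(row("CDS", ex$start[k], ex$end[k], phase,
                     paste0("ID=", id, ".cds;Parent=", id, ".t1")), con)
      cum <- cum + (ex$end[k] - ex$start[k] + 1L)
    }
  }
  invisible(path)
}

#' Read CDS coordinates back from a GFF3 file
#'
#' Thin wrapper around `rtracklayer::import` returning one data.frame of CDS
#' features (contig, start, end, strand, parent).
#'
#' @param path GFF3 file.
#' @return data.frame of CDS features.
#' @export
read_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gff3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  data.frame(contig = as.character(GenomicRanges::seqnames(cds)),
             start = GenomicRanges::start(cds), end = GenomicRanges::end(cds),
             strand = as.character(GenomicRanges::strand(cds)),
             parent = vapply(cds$Parent, `[`, character(1), 1),
             stringsAsFactors = FALSE)
}
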