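#' @importFrom stats setNames
NULL

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")
DNA_ALPHABET <- c("A","C","G","T")

#' Create a validated sequence set
#'
#' A sequence set is a named character vector of upper-case residue strings,
#' with a `kind` attribute (`"peptide"` or `"dna"`). Peptide sequences may
#' contain `X` (unknown residue), nucleotide sequences may contain `N`.
#'
#' @param x named character vector of sequences.
#' @param kind `"peptide"` or `"dna"`.
#' @return the validated set (class `seqset`).
#' @export
seqset <- function(x, kind = c("peptide", "dna")) {
  kind <- match.arg(kind)
  if (length(x) == 0) stop("empty sequence set")
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids))) stop("all sequences must be named")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  x <- toupper(x)
  if (any(!nzchar(x))) stop("empty sequence: ", paste(ids[!nzchar(x)], collapse = ", "))
  allowed <- if (kind == "peptide") c(AA_ALPHABET, "X", "*") else c(DNA_ALPHABET, "N")
  bad <- vapply(x, function(s) {
    any(!strsplit(s, "")[[1]] %in% allowed)
  }, logical(1))
  if (any(bad)) {
    stop("sequence(s) with characters outside the ", kind, " alphabet: ",
         paste(ids[bad], collapse = ", "))
  }
  structure(x, kind = kind, class = "seqset")
}

seq_kind <- function(x) attr(x, "kind")

#' Read a FASTA file into a sequence set
#'
#' Headers are truncated at the first whitespace character. Sequences are
#' stored upper-case; gzip-compressed files are accepted.
#'
#' @param path FASTA file.
#' @param kind `"peptide"` or `"dna"`.
#' @return a [seqset()].
#' @export
read_fasta <- function(path, kind = c("peptide", "dna")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no sequences in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqset(setNames(as.character(set), ids), kind = kind)
}

#' Write a sequence set to FASTA
#'
#' @param seqs a [seqset()] or named character vector.
#' @param path output file.
#' @param width line width for wrapping (default 80).
#' @export
write_fasta <- function(seqs, path, width = 80) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of a nucleotide sequence
#'
#' Length-preserving involution; `N` maps to `N`.
#'
#' @param seq a single nucleotide string or a character vector of them.
#' @return the reverse complement(s), names preserved.
#' @export
reverse_complement <- function(seq) {
  if (!is.null(attr(seq, "kind")) && attr(seq, "kind") != "dna") {
    stop("reverse_complement requires nucleotide input")
  }
  out <- vapply(seq, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1))
  names(out) <- names(seq)
  out
}

#' Translate one reading frame of a nucleotide sequence
#'
#' Standard genetic code; stop codons are rendered as `*`, any codon
#' containing `N` translates to `X`, and a trailing partial codon is dropped.
#' Frames are numbered `+1, +2, +3` on the forward strand and `-1, -2, -3`
#' on the reverse complement.
#'
#' @param seq a single nucleotide string.
#' @param frame integer in `c(1, 2, 3, -1, -2, -3)`.
#' @return the peptide string (possibly empty).
#' @export
translate_frame <- function(seq, frame) {
  if (!frame %in% c(1L, 2L, 3L, -1L, -2L, -3L)) {
    stop("frame must be one of +1, +2, +3, -1, -2, -3")
  }
  s <- toupper(as.character(seq)[[1]])
  if (frame < 0) s <- reverse_complement(s)
  off <- abs(frame)
  n_codons <- (nchar(s) - off + 1) %/% 3
  if (n_codons <= 0) return("")
  starts <- off + 3 * (seq_len(n_codons) - 1)
  codons <- substring(s, starts, starts + 2)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Six-frame translation into stop-free peptide fragments
#'
#' Each reading frame is translated and split at stop codons; maximal
#' stop-free runs of at least `min_fragment_len` residues are reported with
#' coordinates sufficient to re-derive them from the parent sequence.
#' `start_nt` is the forward-strand position of the leftmost base covered by
#' the fragment, so that for forward frames the fragment re-translates from
#' `substring(seq, start_nt, start_nt + 3 * nchar(residues) - 1)` in frame +1,
#' and for reverse frames from the reverse complement of that same substring.
#'
#' @param seq a single nucleotide string (optionally named).
#' @param min_fragment_len minimum fragment length in residues (default 50).
#' @param parent_id id recorded for the parent (default the sequence's name).
#' @return data.frame with columns `parent_id, frame, start_nt, aa_offset,
#'   residues` (`aa_offset` is the 0-based residue offset within the frame's
#'   full translation).
#' @export
six_frame_fragments <- function(seq, min_fragment_len = 50, parent_id = NULL) {
  stopifnot(min_fragment_len >= 1)
  if (is.null(parent_id)) parent_id <- if (!is.null(names(seq))) names(seq)[1] else "seq"
  s <- toupper(as.character(seq)[[1]])
  L <- nchar(s)
  out <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    pep <- translate_frame(s, frame)
    if (!nzchar(pep)) next
    runs <- strsplit(pep, "*", fixed = TRUE)[[1]]
    offs <- cumsum(c(0L, nchar(runs) + 1L))[seq_along(runs)]
    keep <- nchar(runs) >= min_fragment_len
    if (!any(keep)) next
    runs <- runs[keep]; offs <- offs[keep]
    # forward-strand coordinate of the leftmost base of the first codon
    start_nt <- if (frame > 0) {
      frame + 3L * offs
    } else {
      # reverse frames run right-to-left on the forward strand
      (L - abs(frame) + 1L) - 3L * offs - 3L * (nchar(runs) - 1L) - 2L
    }
    out[[length(out) + 1L]] <- data.frame(
      parent_id = parent_id, frame = frame, start_nt = start_nt,
      aa_offset = offs, residues = runs, stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) {
    return(data.frame(parent_id = character(), frame = integer(),
                      start_nt = integer(), aa_offset = integer(),
                      residues = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
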