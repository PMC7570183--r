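#' Build a global multiple alignment of peptide sequences
#'
#' Uses the external MAFFT binary when present on the PATH (engine
#' `"auto"`/`"mafft"`); otherwise a deterministic internal center-star
#' progressive alignment (pairwise global alignments anchored on the longest
#' input sequence, merged through the shared center row).
#'
#' @param seqs named character vector / [seqset()] of at least 2 peptides.
#' @param engine `"auto"`, `"mafft"` or `"internal"`.
#' @param scoring a [scoring_scheme()] (internal engine only).
#' @return an `msa`: named character vector of equal-length aligned rows,
#'   gap symbol `-`; degapping any row reproduces its input sequence.
#' @export
build_msa <- function(seqs, engine = c("auto", "mafft", "internal"),
                      scoring = scoring_scheme()) {
  engine <- match.arg(engine)
  seqs <- stats::setNames(toupper(as.character(seqs)), names(seqs))
  if (length(seqs) < 2) stop("build_msa needs at least 2 sequences")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids in MSA input")
  have_mafft <- nzchar(Sys.which("mafft"))
  if (engine == "mafft" && !have_mafft) {
    stop("MAFFT requested but the 'mafft' binary is not on the PATH")
  }
  use_mafft <- engine == "mafft" || (engine == "auto" && have_mafft)
  if (use_mafft) {
    tf <- tempfile(fileext = ".fa"); of <- tempfile(fileext = ".fa")
    on.exit(unlink(c(tf, of)))
    write_fasta(seqs, tf)
    system2("mafft", c("--quiet", "--anysymbol", "--retree", "2", tf),
            stdout = of, stderr = FALSE)
    aln <- Biostrings::readBStringSet(of)
    rows <- stats::setNames(toupper(as.character(aln)),
                            sub("\\s.*$", "", names(aln)))
    rows <- rows[names(seqs)]
  } else {
    rows <- center_star_msa(seqs, scoring)
  }
  structure(rows, class = "msa")
}

# deterministic center-star progressive alignment
center_star_msa <- function(seqs, scoring) {
  center_i <- order(-nchar(seqs), names(seqs))[1]
  center <- seqs[[center_i]]
  others <- seqs[-center_i]
  clen <- nchar(center)
  # per sequence: insertion counts before each center position (1..clen+1)
  # and the subject characters emitted per alignment column
  aligned <- list()
  ins <- matrix(0L, nrow = length(others), ncol = clen + 1)
  for (i in seq_along(others)) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAString(others[[i]]),
      subject = Biostrings::AAString(center), type = "global",
      substitutionMatrix = scoring$mat, gapOpening = scoring$gap_open,
      gapExtension = scoring$gap_ext)
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    cpos <- 1L
    for (k in seq_along(s)) {
      if (s[k] == "-") ins[i, cpos] <- ins[i, cpos] + 1L else cpos <- cpos + 1L
    }
    aligned[[i]] <- list(p = p, s = s)
  }
  master_ins <- if (length(others)) apply(ins, 2, max) else rep(0L, clen + 1)
  pad <- function(chars, nins_here, target) {
    c(chars, rep("-", target - nins_here))
  }
  # center row
  cchars <- strsplit(center, "")[[1]]
  crow <- character(0)
  for (j in seq_len(clen + 1)) {
    crow <- c(crow, rep("-", master_ins[j]))
    if (j <= clen) crow <- c(crow, cchars[j])
  }
  rows <- stats::setNames(vector("list", length(seqs)), names(seqs))
  rows[[names(seqs)[center_i]]] <- paste(crow, collapse = "")
  for (i in seq_along(others)) {
    p <- aligned[[i]]$p; s <- aligned[[i]]$s
    out <- character(0)
    cpos <- 1L; block <- character(0)
    for (k in seq_along(s)) {
      if (s[k] == "-") {
        block <- c(block, p[k])
      } else {
        out <- c(out, block, rep("-", master_ins[cpos] - length(block)), p[k])
        block <- character(0)
        cpos <- cpos + 1L
      }
    }
    out <- c(out, block, rep("-", master_ins[clen + 1] - length(block)))
    rows[[names(others)[i]]] <- paste(out, collapse = "")
  }
  unlist(rows)
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa>", length(x), "rows x", nchar(x[[1]]), "columns\n")
  invisible(x)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(unclass(msa), ""))
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Remove low-occupancy alignment columns
#'
#' Retains exactly the columns whose non-gap fraction is at least
#' `min_occupancy`; columns below the threshold (default: fewer than 10% of
#' rows occupied) are removed before tree construction.
#'
#' @param msa an `msa`.
#' @param min_occupancy minimum non-gap fraction (default 0.1).
#' @return the filtered `msa`.
#' @export
occupancy_filter <- function(msa, min_occupancy = 0.1) {
  m <- msa_matrix(msa)
  occ <- colMeans(m != "-")
  keep <- occ >= min_occupancy
  structure(stats::setNames(apply(m[, keep, drop = FALSE], 1, paste,
                                  collapse = ""), names(msa)),
            class = "msa")
}

# pairwise p-distance over columns where both rows are non-gap
msa_p_distance <- function(msa) {
  m <- msa_matrix(msa)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- m[i, ] != "-" & m[j, ] != "-"
      d[i, j] <- d[j, i] <- if (!any(shared)) 1 else
        mean(m[i, shared] != m[j, shared])
    }
  }
  d
}

#' Neighbor-joining tree from a peptide alignment
#'
#' p-distances over shared non-gap columns, NJ via \pkg{ape}; negative branch
#' lengths are clamped to zero so patristic distances stay non-negative.
#'
#' @param msa an `msa` with at least 3 rows.
#' @return an `ape::phylo` tree.
#' @export
build_nj_tree <- function(msa) {
  d <- msa_p_distance(msa)
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

pool_baits <- function(bait_sets) {
  out <- character(0)
  for (bs in bait_sets) {
    for (id in names(bs$baits)) out[id] <- bs$baits[[id]]
  }
  out
}

bait_reaction_map <- function(bait_sets) {
  out <- list()
  for (bs in bait_sets) {
    for (id in names(bs$baits)) {
      if (!is.null(out[[id]]) && out[[id]] != bs$reaction) {
        stop("bait id '", id, "' occurs in multiple reactions; ids must be unique")
      }
      out[[id]] <- bs$reaction
    }
  }
  unlist(out)
}

empty_assignments <- function() {
  data.frame(candidate_id = character(), reaction = character(),
             closest_bait_id = character(), metric = character(),
             value = numeric(), co_candidates = character(),
             stringsAsFactors = FALSE)
}

assign_from_distances <- function(cand_ids, bait_ids, dist_to, metric,
                                  reaction_of, k_nearest, tiebreak_score = NULL) {
  rows <- lapply(cand_ids, function(cid) {
    d <- dist_to[[cid]]
    ord <- order(d, names(d))
    if (!is.null(tiebreak_score)) {
      ord <- order(d, -tiebreak_score[[cid]], names(d))
    }
    nearest <- names(d)[ord[1]]
    k <- min(k_nearest, length(d))
    near_rxn <- unique(unname(reaction_of[names(d)[ord[seq_len(k)]]]))
    co <- setdiff(near_rxn, reaction_of[[nearest]])
    data.frame(candidate_id = cid, reaction = unname(reaction_of[[nearest]]),
               closest_bait_id = nearest, metric = metric,
               value = unname(d[ord[1]]),
               co_candidates = paste(co, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign candidate function from the closest bait in a phylogenetic tree
#'
#' Candidates and all baits are aligned together, low-occupancy columns are
#' removed, a neighbor-joining tree is built, and each candidate inherits the
#' reaction of its minimum-patristic-distance bait. When the `k_nearest`
#' nearest baits span several reactions, the alternatives are recorded in
#' `co_candidates`. With fewer than 4 leaves (or on tree failure) the
#' alignment-similarity classifier is used instead, with a warning.
#'
#' @param candidates named peptide character vector / [seqset()].
#' @param bait_sets list of [bait_set()] objects (one or more reactions).
#' @param k_nearest how many nearest baits to inspect for co-candidate
#'   reactions (default 3).
#' @param msa_engine passed to [build_msa()].
#' @param min_occupancy column filter threshold before tree building.
#' @return data.frame: `candidate_id, reaction, closest_bait_id, metric,
#'   value, co_candidates`; the NJ tree is attached as attribute `"tree"`,
#'   the alignment as `"msa"`.
#' @export
classify_by_tree <- function(candidates, bait_sets, k_nearest = 3,
                             msa_engine = "auto", min_occupancy = 0.1) {
  candidates <- stats::setNames(toupper(as.character(candidates)),
                                names(candidates))
  if (length(candidates) == 0) return(empty_assignments())
  reaction_of <- bait_reaction_map(bait_sets)
  baits <- pool_baits(bait_sets)
  all_seqs <- c(baits, candidates)
  if (length(all_seqs) < 4) {
    warning("fewer than 4 leaves; falling back to alignment similarity")
    return(classify_by_similarity(candidates, bait_sets, k_nearest))
  }
  msa <- build_msa(all_seqs, engine = msa_engine)
  trimmed <- occupancy_filter(msa, min_occupancy)
  tr <- tryCatch(build_nj_tree(trimmed), error = function(e) NULL)
  if (is.null(tr)) {
    warning("tree construction failed; falling back to alignment similarity")
    return(classify_by_similarity(candidates, bait_sets, k_nearest))
  }
  pat <- stats::cophenetic(tr)
  dist_to <- lapply(names(candidates), function(cid) {
    pat[cid, names(reaction_of)]
  })
  names(dist_to) <- names(candidates)
  out <- assign_from_distances(names(candidates), names(reaction_of), dist_to,
                               "tree_distance", reaction_of, k_nearest)
  out <- out[order(out$candidate_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tree") <- tr
  attr(out, "msa") <- msa
  out
}

#' Assign candidate function from the most similar bait in global alignments
#'
#' Each candidate is aligned globally against every bait; the reaction of the
#' highest-identity bait is transferred (ties broken by higher raw alignment
#' score, then bait id). Serves as the classification route when no tree can
#' be built.
#'
#' @inheritParams classify_by_tree
#' @param scoring a [scoring_scheme()].
#' @return data.frame as in [classify_by_tree()] with `metric`
#'   `"alignment_similarity"` and `value` the global-alignment identity.
#' @export
classify_by_similarity <- function(candidates, bait_sets, k_nearest = 3,
                                   scoring = scoring_scheme()) {
  candidates <- stats::setNames(toupper(as.character(candidates)),
                                names(candidates))
  if (length(candidates) == 0) return(empty_assignments())
  reaction_of <- bait_reaction_map(bait_sets)
  baits <- as.list(pool_baits(bait_sets))
  cand_set <- Biostrings::AAStringSet(candidates)
  sim <- matrix(NA_real_, length(candidates), length(baits),
                dimnames = list(names(candidates), names(baits)))
  raw <- sim
  for (b in names(baits)) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = cand_set, subject = Biostrings::AAString(baits[[b]]),
      type = "global", substitutionMatrix = scoring$mat,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
    sim[, b] <- Biostrings::pid(pa, type = "PID1") / 100
    raw[, b] <- Biostrings::score(pa)
  }
  dist_to <- lapply(names(candidates), function(cid) 1 - sim[cid, ])
  names(dist_to) <- names(candidates)
  tiebreak <- lapply(names(candidates), function(cid) raw[cid, ])
  names(tiebreak) <- names(candidates)
  out <- assign_from_distances(names(candidates), names(baits), dist_to,
                               "alignment_similarity", reaction_of, k_nearest,
                               tiebreak_score = tiebreak)
  out$value <- 1 - out$value
  out <- out[order(out$candidate_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
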