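# biochemical groups used by the opt-in "similar residue" mode
AA_GROUPS <- list(
  aliphatic = c("A", "G", "I", "L", "V", "M"),
  aromatic  = c("F", "W", "Y"),
  polar     = c("S", "T", "N", "Q", "C"),
  acidic    = c("D", "E"),
  basic     = c("K", "R", "H"),
  special   = c("P")
)

aa_group <- function(aa) {
  for (g in names(AA_GROUPS)) if (aa %in% AA_GROUPS[[g]]) return(g)
  NA_character_
}

# column index of each degapped position of one MSA row
row_columns <- function(msa, id) {
  chars <- strsplit(unclass(msa)[[id]], "")[[1]]
  which(chars != "-")
}

#' Map reference residue positions onto a candidate through the alignment
#'
#' For each 1-based position on the degapped reference, finds the alignment
#' column holding it and reports the candidate's residue index in that
#' column, or `"absent"` when the candidate has a gap there.
#'
#' @param msa an `msa` containing both rows.
#' @param reference_id,candidate_id row ids.
#' @param positions integer positions on the degapped reference.
#' @return data.frame: `ref_position, column, cand_position`
#'   (`cand_position` is `NA` when absent), `observed` (candidate character,
#'   `-` for a gap).
#' @export
map_positions <- function(msa, reference_id, candidate_id, positions) {
  rows <- unclass(msa)
  if (!reference_id %in% names(rows)) stop("reference id not in alignment")
  if (!candidate_id %in% names(rows)) stop("candidate id not in alignment")
  ref_cols <- row_columns(msa, reference_id)
  if (any(positions < 1 | positions > length(ref_cols))) {
    stop("position beyond reference length (", length(ref_cols), ")")
  }
  cand_chars <- strsplit(rows[[candidate_id]], "")[[1]]
  cand_index <- cumsum(cand_chars != "-")
  cols <- ref_cols[positions]
  obs <- cand_chars[cols]
  data.frame(
    ref_position = positions, column = cols,
    cand_position = ifelse(obs == "-", NA_integer_, cand_index[cols]),
    observed = obs, stringsAsFactors = FALSE)
}

#' Check functionally relevant residues of one candidate
#'
#' Every residue rule of the reference specification is mapped through the
#' alignment onto the candidate and the observed residue is compared with
#' the allowed set. With `similar_mode` a residue sharing the biochemical
#' group of an allowed residue is reported as `similar` rather than
#' `mismatch`.
#'
#' @param msa an `msa` containing the reference and the candidate.
#' @param spec a `reference_spec`.
#' @param candidate_id row id of the candidate.
#' @param similar_mode accept biochemically similar residues (default FALSE).
#' @param reference_id row id of the reference (default: `spec` reaction's
#'   reference must be supplied by the caller via this argument).
#' @return data.frame: `label, ref_position, cand_position, allowed,
#'   observed, status` with status in `match/similar/mismatch/absent`.
#' @export
check_residues <- function(msa, spec, candidate_id, reference_id,
                           similar_mode = FALSE) {
  rules <- spec$residue_rules
  if (nrow(rules) == 0) {
    return(data.frame(label = character(), ref_position = integer(),
                      cand_position = integer(), allowed = character(),
                      observed = character(), status = character(),
                      stringsAsFactors = FALSE))
  }
  mp <- map_positions(msa, reference_id, candidate_id, rules$position)
  status <- character(nrow(rules))
  for (i in seq_len(nrow(rules))) {
    obs <- mp$observed[i]
    allowed <- strsplit(rules$allowed[i], "")[[1]]
    status[i] <- if (obs == "-") {
      "absent"
    } else if (obs %in% allowed) {
      "match"
    } else if (similar_mode && !is.na(aa_group(obs)) &&
               aa_group(obs) %in% vapply(allowed, aa_group, character(1))) {
      "similar"
    } else {
      "mismatch"
    }
  }
  data.frame(label = rules$label, ref_position = rules$position,
             cand_position = mp$cand_position, allowed = rules$allowed,
             observed = mp$observed, status = status, stringsAsFactors = FALSE)
}

#' Check conservation of reference domains in one candidate
#'
#' Identity is computed over the alignment columns covering the reference
#' domain span (candidate gaps count as mismatches); a domain is conserved
#' when identity reaches the rule's `min_identity`.
#'
#' @inheritParams check_residues
#' @return data.frame: `name, start, end, identity, min_identity, conserved`.
#' @export
check_domains <- function(msa, spec, candidate_id, reference_id) {
  rules <- spec$domain_rules
  if (nrow(rules) == 0) {
    return(data.frame(name = character(), start = integer(), end = integer(),
                      identity = numeric(), min_identity = numeric(),
                      conserved = logical(), stringsAsFactors = FALSE))
  }
  rows <- unclass(msa)
  ref_cols <- row_columns(msa, reference_id)
  ref_chars <- strsplit(rows[[reference_id]], "")[[1]]
  cand_chars <- strsplit(rows[[candidate_id]], "")[[1]]
  out <- lapply(seq_len(nrow(rules)), function(i) {
    cols <- ref_cols[rules$start[i]:rules$end[i]]
    ident <- mean(ref_chars[cols] == cand_chars[cols] & cand_chars[cols] != "-")
    data.frame(name = rules$name[i], start = rules$start[i],
               end = rules$end[i], identity = ident,
               min_identity = rules$min_identity[i],
               conserved = ident >= rules$min_identity[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Predict enzyme functionality from residue and domain checks
#'
#' A candidate is predicted `functional` only when every residue rule matches
#' (or is `similar`, when that mode was used for the checks) and every domain
#' is conserved; any violated rule is named in the call, never dropped. With
#' no rules configured the prediction is vacuously `functional`.
#'
#' @param candidate_id candidate id.
#' @param reaction reaction label.
#' @param residue_checks output of [check_residues()].
#' @param domain_checks output of [check_domains()].
#' @return a `functionality_call`: list with `candidate_id, reaction,
#'   residue_checks, domain_checks, prediction, violations, notes`.
#' @export
predict_functionality <- function(candidate_id, reaction, residue_checks,
                                  domain_checks) {
  bad_res <- residue_checks[!residue_checks$status %in% c("match", "similar"), ,
                            drop = FALSE]
  bad_dom <- domain_checks[!domain_checks$conserved, , drop = FALSE]
  violations <- c(
    if (nrow(bad_res)) sprintf("%s: expected [%s] at reference position %d, observed %s (%s)",
                               bad_res$label, bad_res$allowed,
                               bad_res$ref_position, bad_res$observed,
                               bad_res$status),
    if (nrow(bad_dom)) sprintf("domain %s (%d-%d) not conserved: identity %.2f < %.2f",
                               bad_dom$name, bad_dom$start, bad_dom$end,
                               bad_dom$identity, bad_dom$min_identity))
  notes <- character(0)
  if (nrow(residue_checks) == 0 && nrow(domain_checks) == 0) {
    notes <- "no residue or domain rules configured; functionality not assessed"
  }
  structure(list(
    candidate_id = candidate_id, reaction = reaction,
    residue_checks = residue_checks, domain_checks = domain_checks,
    prediction = if (length(violations)) "possibly_nonfunctional" else "functional",
    violations = violations, notes = notes),
    class = "functionality_call")
}

#' @export
print.functionality_call <- function(x, ...) {
  cat("<functionality_call>", x$candidate_id, "(", x$reaction, "):",
      x$prediction, "\n")
  if (length(x$violations)) cat(paste0("  - ", x$violations, "\n"), sep = "")
  invisible(x)
}

#' Discover contrasting residues between two sequence families
#'
#' Both families are aligned together; a column is reported when, ignoring
#' gaps, at least a `purity` fraction of each family's rows carries residues
#' and the two residue sets observed at that purity level are disjoint.
#' Positions are reported on the degapped coordinates of a designated
#' reference from the first set.
#'
#' @param set_a,set_b named peptide character vectors (non-empty).
#' @param purity minimum within-family fraction supporting the contrast
#'   (default 0.9); gap characters are ignored in the purity counts.
#' @param reference_id id of the position-defining sequence (default: first
#'   id of `set_a`).
#' @param msa_engine passed to [build_msa()].
#' @return data.frame: `position` (on the reference; `NA` when the reference
#'   is gapped in that column), `column`, `residues_a`, `residues_b`.
#' @export
contrasting_residues <- function(set_a, set_b, purity = 0.9,
                                 reference_id = NULL, msa_engine = "auto") {
  set_a <- stats::setNames(toupper(as.character(set_a)), names(set_a))
  set_b <- stats::setNames(toupper(as.character(set_b)), names(set_b))
  stopifnot(length(set_a) >= 1, length(set_b) >= 1)
  if (is.null(reference_id)) reference_id <- names(set_a)[1]
  ids_b <- names(set_b)
  overlap <- intersect(names(set_a), ids_b)
  if (length(overlap)) {
    ids_b <- ifelse(ids_b %in% names(set_a), paste0(ids_b, "#b"), ids_b)
    names(set_b) <- ids_b
  }
  msa <- build_msa(c(set_a, set_b), engine = msa_engine)
  m <- msa_matrix(msa)
  a_rows <- match(names(set_a), names(msa))
  b_rows <- match(ids_b, names(msa))
  ref_chars <- m[match(reference_id, names(msa)), ]
  ref_pos <- cumsum(ref_chars != "-")
  out <- list()
  for (col in seq_len(ncol(m))) {
    va <- m[a_rows, col]; vb <- m[b_rows, col]
    va <- va[va != "-"]; vb <- vb[vb != "-"]
    if (length(va) < purity * length(a_rows) ||
        length(vb) < purity * length(b_rows)) next
    # smallest residue set (most frequent first) covering >= purity of each
    # family's non-gap rows; the column contrasts when the two are disjoint
    cover <- function(v) {
      tt <- sort(table(v), decreasing = TRUE)
      cs <- cumsum(as.numeric(tt))
      k <- which(cs >= purity * length(v))[1]
      names(tt)[seq_len(k)]
    }
    ra <- cover(va)
    rb <- cover(vb)
    if (length(intersect(ra, rb)) == 0) {
      out[[length(out) + 1L]] <- data.frame(
        position = if (ref_chars[col] == "-") NA_integer_ else ref_pos[col],
        column = col, residues_a = paste(ra, collapse = ""),
        residues_b = paste(rb, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(position = integer(), column = integer(),
                      residues_a = character(), residues_b = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$column), , drop = FALSE]
}

#' Append substrate-specificity annotations to a functionality call
#'
#' Looks up the candidate's residue at each specificity position (declared in
#' the rules table relative to a sub-domain anchor on the reference) and
#' appends the matching annotation as a note. The functional /
#' possibly-nonfunctional prediction is never altered.
#'
#' @param call a `functionality_call`.
#' @param spec a `reference_spec` with `specificity_rules`.
#' @param msa an `msa` containing reference and candidate.
#' @param reference_id row id of the reference.
#' @return the updated `functionality_call`.
#' @export
annotate_specificity <- function(call, spec, msa, reference_id) {
  rules <- spec$specificity_rules
  if (is.null(rules) || nrow(rules) == 0) return(call)
  for (pos in unique(rules$position)) {
    mp <- map_positions(msa, reference_id, call$candidate_id, pos)
    obs <- mp$observed[1]
    hit <- rules[rules$position == pos & rules$residue == obs, , drop = FALSE]
    note <- if (nrow(hit)) {
      sprintf("specificity position %d: %s -> %s", pos, obs, hit$annotation[1])
    } else {
      sprintf("specificity position %d: observed %s (no annotation)", pos, obs)
    }
    call$notes <- c(call$notes, note)
  }
  call
}
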