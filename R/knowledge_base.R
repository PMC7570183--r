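#' Load a bait set for one reaction
#'
#' All bait peptides for one reaction of the pathway live in one FASTA file;
#' one of them is designated the reference sequence on which functionally
#' relevant residue positions and domain spans are defined.
#'
#' @param fasta_path peptide FASTA file with all baits for the reaction.
#' @param reference_id FASTA id (header token up to first whitespace) of the
#'   designated reference; must occur exactly once in the file.
#' @param reaction reaction label (default: file name without extension).
#' @return an object of class `bait_set` with elements `reaction`, `baits`
#'   (a peptide [seqset()]) and `reference_id`.
#' @export
load_bait_set <- function(fasta_path, reference_id, reaction = NULL) {
  if (!file.exists(fasta_path)) stop("bait FASTA not found: ", fasta_path)
  if (is.null(reaction)) {
    reaction <- sub("\\.(fa|fasta|faa|fa\\.gz|fasta\\.gz)$", "",
                    basename(fasta_path), ignore.case = TRUE)
  }
  baits <- read_fasta(fasta_path, kind = "peptide")
  if (!reference_id %in% names(baits)) {
    stop("reference id '", reference_id, "' not present in ", fasta_path)
  }
  bait_set(reaction, baits, reference_id)
}

#' Construct a bait set from in-memory sequences
#'
#' @param reaction reaction label (e.g. `"CHS"`).
#' @param baits peptide [seqset()] or named character vector.
#' @param reference_id id of the designated reference among `baits`.
#' @return a `bait_set` object.
#' @export
bait_set <- function(reaction, baits, reference_id) {
  if (!inherits(baits, "seqset")) baits <- seqset(baits, kind = "peptide")
  stopifnot(length(baits) >= 1)
  if (sum(names(baits) == reference_id) != 1) {
    stop("reference id '", reference_id, "' must name exactly one bait")
  }
  structure(list(reaction = reaction, baits = baits,
                 reference_id = reference_id),
            class = "bait_set")
}

#' @export
print.bait_set <- function(x, ...) {
  cat("<bait_set> reaction:", x$reaction, "|", length(x$baits),
      "baits | reference:", x$reference_id, "\n")
  invisible(x)
}

reference_seq <- function(bs) unname(bs$baits[[bs$reference_id]])

#' Load residue/domain rules for one reaction
#'
#' The rules table is plain text, one rule per line, `#` starting a comment.
#' Three row shapes are understood:
#' \describe{
#'   \item{residue}{`<position> <allowed residues> [label]`, e.g.
#'     `166 Q CHS-diagnostic`; several allowed one-letter codes may be given
#'     as one string (`ILV`).}
#'   \item{domain}{`<start>-<end> <name> [min_identity]`, e.g.
#'     `313-329 malonyl-CoA-motif 0.6`.}
#'   \item{specificity}{tab-separated:
#'     `specificity <anchor> <offset> <residue>=<annotation> ...`, declaring
#'     substrate-specificity readouts at position `anchor + offset - 1` of
#'     the reference (the anchor names the start of a sub-domain so that
#'     "position 3 of the domain" is well defined).}
#' }
#' All positions are 1-based on the designated reference peptide and are
#' validated against its length.
#'
#' @param table_path rules file.
#' @param bait_set the reaction's [bait_set()].
#' @param default_min_identity domain conservation threshold used when a
#'   domain row does not state one (default 0.6).
#' @return an object of class `reference_spec` with data.frames
#'   `residue_rules` (position, allowed, label), `domain_rules`
#'   (start, end, name, min_identity) and `specificity_rules`
#'   (position, residue, annotation).
#' @export
load_reference_spec <- function(table_path, bait_set,
                                default_min_identity = 0.6) {
  if (!file.exists(table_path)) stop("rules table not found: ", table_path)
  ref <- reference_seq(bait_set)
  ref_len <- nchar(ref)
  lines <- readLines(table_path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  res <- list(); dom <- list(); spc <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) == 1) f <- strsplit(ln, "\\s+")[[1]]
    if (tolower(f[1]) == "specificity") {
      if (length(f) < 4) stop("malformed specificity row: ", ln)
      anchor <- as.integer(f[2]); offset <- as.integer(f[3])
      pos <- anchor + offset - 1L
      if (is.na(pos) || pos < 1 || pos > ref_len) {
        stop("specificity position out of reference range in row: ", ln)
      }
      for (tok in f[-(1:3)]) {
        kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
        if (length(kv) != 2) stop("malformed residue=annotation token: ", tok)
        spc[[length(spc) + 1L]] <- data.frame(
          position = pos, residue = toupper(kv[1]), annotation = kv[2],
          stringsAsFactors = FALSE)
      }
    } else if (grepl("^[0-9]+-[0-9]+$", f[1])) {
      se <- as.integer(strsplit(f[1], "-", fixed = TRUE)[[1]])
      if (se[1] > se[2] || se[1] < 1 || se[2] > ref_len) {
        stop("domain span out of reference range (1-", ref_len, ") in row: ", ln)
      }
      mi <- if (length(f) >= 3 && grepl("^[0-9.]+$", f[3])) as.numeric(f[3]) else default_min_identity
      dom[[length(dom) + 1L]] <- data.frame(
        start = se[1], end = se[2],
        name = if (length(f) >= 2) f[2] else paste0("domain_", se[1], "_", se[2]),
        min_identity = mi, stringsAsFactors = FALSE)
    } else if (grepl("^[0-9]+$", f[1])) {
      pos <- as.integer(f[1])
      if (pos < 1 || pos > ref_len) {
        stop("residue position ", pos, " out of reference range (1-", ref_len,
             ") in row: ", ln)
      }
      allowed <- toupper(f[2])
      if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", allowed)) {
        stop("unknown amino-acid code in allowed set of row: ", ln)
      }
      res[[length(res) + 1L]] <- data.frame(
        position = pos, allowed = allowed,
        label = if (length(f) >= 3) paste(f[-(1:2)], collapse = " ") else paste0("pos", pos),
        stringsAsFactors = FALSE)
    } else {
      stop("unparseable rules row: ", ln)
    }
  }
  bind <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  residue_rules <- bind(res, data.frame(position = integer(), allowed = character(),
                                        label = character(), stringsAsFactors = FALSE))
  residue_rules <- residue_rules[order(residue_rules$position), , drop = FALSE]
  rownames(residue_rules) <- NULL
  structure(list(
    reaction = bait_set$reaction,
    residue_rules = residue_rules,
    domain_rules = bind(dom, data.frame(start = integer(), end = integer(),
                                        name = character(), min_identity = numeric(),
                                        stringsAsFactors = FALSE)),
    specificity_rules = bind(spc, data.frame(position = integer(), residue = character(),
                                             annotation = character(), stringsAsFactors = FALSE))
  ), class = "reference_spec")
}

#' @export
print.reference_spec <- function(x, ...) {
  cat("<reference_spec>", x$reaction, "|", nrow(x$residue_rules), "residue rules |",
      nrow(x$domain_rules), "domain rules |", nrow(x$specificity_rules),
      "specificity rules\n")
  invisible(x)
}

#' Load a whole knowledge base directory
#'
#' Expects a plain-text config file with tab- or whitespace-separated columns
#' `reaction bait_fasta reference_id [rules_table]`; paths are resolved
#' relative to the config file. Rules tables are optional per reaction.
#'
#' @param config_path config file as described.
#' @return named list of lists with elements `bait_set` and `spec`
#'   (`NULL` when no rules table was given), one per reaction.
#' @export
load_knowledge_base <- function(config_path) {
  if (!file.exists(config_path)) stop("config file not found: ", config_path)
  base <- dirname(config_path)
  lines <- readLines(config_path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kb <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 3) stop("config row needs at least reaction, fasta, reference_id: ", ln)
    resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
    bs <- load_bait_set(resolve(f[2]), f[3], reaction = f[1])
    spec <- if (length(f) >= 4) load_reference_spec(resolve(f[4]), bs) else NULL
    kb[[f[1]]] <- list(bait_set = bs, spec = spec)
  }
  kb
}
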