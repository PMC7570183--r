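#' Assemble a pipeline run configuration
#'
#' @param mode `"pep"`, `"rna"` or `"dna"`.
#' @param subject FASTA of subject sequences (peptide for `pep`, nucleotide
#'   otherwise).
#' @param config knowledge-base config file (see [load_knowledge_base()]).
#' @param out output directory.
#' @param min_identity,min_score_ratio candidate filter thresholds
#'   (defaults 0.40 / 0.30).
#' @param min_occupancy alignment column filter for tree building
#'   (default 0.1).
#' @param min_fragment_len six-frame fragment floor for `rna` mode
#'   (default 50).
#' @param max_intron_len,search_window genome-mode stitching parameters
#'   (defaults 20000 / 30).
#' @param k_nearest nearest baits inspected for co-candidate reactions
#'   (default 3).
#' @param similar_mode accept biochemically similar residues in the residue
#'   screen (default FALSE).
#' @param classifier `"tree"` (default) or `"similarity"`.
#' @param msa_engine passed to [build_msa()].
#' @param search_engine passed to [search_candidates()].
#' @param seed integer recorded in the run log (the pipeline itself is
#'   deterministic; the seed governs fixture generation only).
#' @return a `run_config` list.
#' @export
run_config <- function(mode, subject, config, out,
                       min_identity = 0.40, min_score_ratio = 0.30,
                       min_occupancy = 0.1, min_fragment_len = 50,
                       max_intron_len = 20000, search_window = 30,
                       k_nearest = 3, similar_mode = FALSE,
                       classifier = c("tree", "similarity"),
                       msa_engine = "auto", search_engine = "internal",
                       seed = 1) {
  structure(list(mode = match.arg(mode, c("pep", "rna", "dna")),
                 subject = subject, config = config, out = out,
                 min_identity = min_identity,
                 min_score_ratio = min_score_ratio,
                 min_occupancy = min_occupancy,
                 min_fragment_len = min_fragment_len,
                 max_intron_len = max_intron_len,
                 search_window = search_window, k_nearest = k_nearest,
                 similar_mode = similar_mode,
                 classifier = match.arg(classifier),
                 msa_engine = msa_engine, search_engine = search_engine,
                 seed = seed),
            class = "run_config")
}

log_stage <- function(log, stage, reaction, n_in, n_out, note = "") {
  rbind(log, data.frame(stage = stage, reaction = reaction, n_in = n_in,
                        n_out = n_out, note = note, stringsAsFactors = FALSE))
}

#' Run the full candidate identification pipeline
#'
#' Per reaction: similarity search of the subjects against the baits
#' (six-frame translation for transcripts; exon grouping and GT-AG isoform
#' stitching for genomes), the dual identity / self-score-ratio filter,
#' global alignment, nearest-bait classification, residue and domain
#' screening and a functionality prediction. Every intermediate result is
#' written into the output directory; identical configuration and inputs
#' give byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `summary` (data.frame), `calls`,
#'   `assignments`, `models` (dna mode), `log`, and `out`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  kb <- load_knowledge_base(config$config)
  subj_kind <- if (config$mode == "pep") "peptide" else "dna"
  subjects <- read_fasta(config$subject, kind = subj_kind)
  scoring <- scoring_scheme()
  log <- data.frame(stage = character(), reaction = character(),
                    n_in = integer(), n_out = integer(), note = character(),
                    stringsAsFactors = FALSE)
  # echo the configuration
  cfg_lines <- vapply(names(unclass(config)), function(k)
    paste0(k, "=", paste(format(config[[k]]), collapse = ",")), character(1))
  writeLines(cfg_lines, file.path(config$out, "run_config.txt"))

  candidates <- character(0)   # named peptide vector, all reactions pooled
  cand_src <- list()           # provenance per candidate id
  all_models <- list()
  errors <- character(0)

  for (rxn in names(kb)) {
    res <- tryCatch({
      bs <- kb[[rxn]]$bait_set
      hits <- search_candidates(bs, subjects, mode = config$mode,
                                scoring = scoring,
                                min_fragment_len = config$min_fragment_len,
                                engine = config$search_engine)
      if (config$mode %in% c("pep", "rna")) {
        kept <- filter_hits(hits, config$min_identity, config$min_score_ratio)
        log <- log_stage(log, "search+filter", rxn, nrow(hits), nrow(kept))
        ids <- unique(kept$subject_id)
        seqs <- if (config$mode == "pep") {
          stats::setNames(unclass(subjects)[ids], ids)
        } else {
          frag_peptides(subjects, ids, config$min_fragment_len)
        }
        for (id in names(seqs)) {
          candidates[id] <- seqs[[id]]
          cand_src[[id]] <- rxn
        }
      } else {
        loci <- group_hits(hits, max_intron_len = config$max_intron_len)
        log <- log_stage(log, "group", rxn, nrow(hits), length(loci))
        models <- lapply(loci, function(lc)
          stitch_isoform(lc, subjects, search_window = config$search_window,
                         bait = bs$baits[[lc$query_id]], scoring = scoring))
        models <- dedup_models(models, reference = reference_seq(bs),
                               scoring = scoring)
        n_part <- sum(vapply(models, function(m)
          m$status != "complete", logical(1)))
        log <- log_stage(log, "stitch", rxn, length(loci), length(models),
                          note = paste0(n_part, " partial"))
        for (m in models) {
          mid <- sprintf("%s_%s_%d", m$contig,
                         if (m$strand == "+") "p" else "m", min(m$exons$start))
          m$model_id <- mid
          all_models[[mid]] <- m
          if (m$status == "complete" && nzchar(m$peptide)) {
            # the ratio filter applies to the assembled isoform
            h <- align_bait_vs_peptides(
              bs$reference_id, reference_seq(bs),
              stats::setNames(list(m$peptide), mid), scoring)
            h$mode <- "pep"
            if (nrow(filter_hits(h, config$min_identity,
                                 config$min_score_ratio)) > 0) {
              candidates[mid] <- m$peptide
              cand_src[[mid]] <- rxn
            }
          }
        }
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      errors <- c(errors, paste0(rxn, ": ", res))
      log <- log_stage(log, "error", rxn, NA, NA, note = res)
    }
  }
  candidates <- candidates[!duplicated(names(candidates))]
  log <- log_stage(log, "candidates", "all", length(subjects),
                   length(candidates))

  bait_sets <- lapply(kb, `[[`, "bait_set")
  assignments <- if (length(candidates) == 0) {
    empty_assignments()
  } else if (config$classifier == "tree") {
    classify_by_tree(candidates, bait_sets, k_nearest = config$k_nearest,
                     msa_engine = config$msa_engine,
                     min_occupancy = config$min_occupancy)
  } else {
    classify_by_similarity(candidates, bait_sets,
                           k_nearest = config$k_nearest)
  }

  calls <- list()
  for (rxn in names(kb)) {
    bs <- kb[[rxn]]$bait_set
    spec <- kb[[rxn]]$spec
    ids <- assignments$candidate_id[assignments$reaction == rxn]
    write_fasta(candidates[ids],
                file.path(config$out, paste0("candidates_", rxn, ".fasta")))
    if (length(ids) == 0) next
    msa <- build_msa(c(unclass(bs$baits), candidates[ids]),
                     engine = config$msa_engine)
    write_fasta(unclass(msa), file.path(config$out, paste0("msa_", rxn, ".fasta")))
    if (length(msa) >= 3) {
      tr <- tryCatch(build_nj_tree(occupancy_filter(msa, config$min_occupancy)),
                     error = function(e) NULL)
      if (!is.null(tr)) {
        ape::write.tree(tr, file.path(config$out, paste0("tree_", rxn, ".nwk")))
      }
    }
    res_rows <- list(); dom_rows <- list()
    for (cid in ids) {
      rc <- if (!is.null(spec)) {
        check_residues(msa, spec, cid, bs$reference_id,
                       similar_mode = config$similar_mode)
      } else check_residues(msa, list(residue_rules = data.frame()), cid,
                            bs$reference_id)
      dc <- if (!is.null(spec)) check_domains(msa, spec, cid, bs$reference_id)
            else check_domains(msa, list(domain_rules = data.frame()), cid,
                               bs$reference_id)
      call <- predict_functionality(cid, rxn, rc, dc)
      if (!is.null(spec) && nrow(spec$specificity_rules)) {
        call <- annotate_specificity(call, spec, msa, bs$reference_id)
      }
      calls[[cid]] <- call
      if (nrow(rc)) res_rows[[cid]] <- cbind(reaction = rxn, candidate = cid, rc)
      if (nrow(dc)) dom_rows[[cid]] <- cbind(reaction = rxn, candidate = cid, dc)
    }
    write_tsv(do.call(rbind, res_rows),
              file.path(config$out, paste0("residues_", rxn, ".tsv")))
    write_tsv(do.call(rbind, dom_rows),
              file.path(config$out, paste0("domains_", rxn, ".tsv")))
    log <- log_stage(log, "screen", rxn, length(ids),
                     sum(vapply(calls[ids], function(cl)
                       cl$prediction == "functional", logical(1))))
  }
  if (config$mode == "dna" && length(all_models)) {
    ord <- order(vapply(all_models, function(m) min(m$exons$start), numeric(1)))
    write_gff3(all_models[ord], file.path(config$out, "models.gff3"))
    write_fasta(stats::setNames(
      vapply(all_models[ord], `[[`, character(1), "cds"),
      names(all_models)[ord]), file.path(config$out, "cds.fasta"))
  }
  summary <- summarize(calls, assignments)
  write_tsv(summary, file.path(config$out, "summary.tsv"))
  write_tsv(log, file.path(config$out, "log.tsv"))
  invisible(list(summary = summary, calls = calls, assignments = assignments,
                 models = all_models, candidates = candidates, log = log,
                 errors = errors, out = config$out))
}

# peptide sequences of named six-frame fragments "parent|f<frame>|<start_nt>"
frag_peptides <- function(subjects, frag_ids, min_fragment_len) {
  if (length(frag_ids) == 0) return(character(0))
  parents <- sub("\\|f[+-][0-9]\\|[0-9]+$", "", frag_ids)
  out <- character(0)
  for (p in unique(parents)) {
    ft <- six_frame_fragments(subjects[[p]], min_fragment_len, parent_id = p)
    ids <- sprintf("%s|f%+d|%d", ft$parent_id, ft$frame, ft$start_nt)
    want <- frag_ids[parents == p]
    out[want] <- ft$residues[match(want, ids)]
  }
  out
}

# keep the best model per overlapping genomic region. Competing models of
# one region come from different baits, so raw scores are not comparable;
# rank by alignment score against one common yardstick (the reaction
# reference) when available, else by the self-score-normalized score.
dedup_models <- function(models, reference = NULL, scoring = scoring_scheme()) {
  if (length(models) <= 1) return(models)
  sc <- vapply(models, `[[`, numeric(1), "score")
  sr <- if (!is.null(reference)) {
    vapply(models, function(m) {
      if (!nzchar(m$peptide)) return(-Inf)
      Biostrings::pairwiseAlignment(
        pattern = Biostrings::AAString(m$peptide),
        subject = Biostrings::AAString(reference), type = "local",
        substitutionMatrix = scoring$mat, gapOpening = scoring$gap_open,
        gapExtension = scoring$gap_ext, scoreOnly = TRUE)
    }, numeric(1))
  } else {
    vapply(models, function(m)
      if (is.null(m$score_ratio) || is.na(m$score_ratio)) -Inf
      else m$score_ratio, numeric(1))
  }
  # ties on the common score mean the extra material of a longer model is
  # unsupported by the reference; parsimony prefers the shorter isoform
  plen <- vapply(models, function(m) nchar(m$peptide), integer(1))
  models <- models[order(-sr, plen, -sc)]
  kept <- list()
  for (m in models) {
    s <- min(m$exons$start); e <- max(m$exons$end)
    clash <- any(vapply(kept, function(k)
      k$contig == m$contig && k$strand == m$strand &&
        s <= max(k$exons$end) && e >= min(k$exons$start), logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- m
  }
  kept
}

write_tsv <- function(df, path) {
  if (is.null(df)) {
    df <- data.frame()
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarise functionality calls and assignments into one table
#'
#' @param calls named list of `functionality_call` objects.
#' @param assignments data.frame from [classify_by_tree()] or
#'   [classify_by_similarity()].
#' @return data.frame, one row per candidate: `reaction, candidate_id,
#'   closest_bait_id, metric, value, co_candidates, n_rules, n_matched,
#'   prediction, notes`; sorted by reaction then by decreasing closeness.
#' @export
summarize <- function(calls, assignments) {
  if (length(calls) == 0 || nrow(assignments) == 0) {
    return(data.frame(reaction = character(), candidate_id = character(),
                      closest_bait_id = character(), metric = character(),
                      value = numeric(), co_candidates = character(),
                      n_rules = integer(), n_matched = integer(),
                      prediction = character(), notes = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(names(calls), function(cid) {
    a <- assignments[assignments$candidate_id == cid, , drop = FALSE]
    cl <- calls[[cid]]
    nr <- nrow(cl$residue_checks) + nrow(cl$domain_checks)
    nm <- sum(cl$residue_checks$status %in% c("match", "similar")) +
      sum(cl$domain_checks$conserved)
    data.frame(reaction = cl$reaction, candidate_id = cid,
               closest_bait_id = a$closest_bait_id[1], metric = a$metric[1],
               value = a$value[1], co_candidates = a$co_candidates[1],
               n_rules = nr, n_matched = nm, prediction = cl$prediction,
               notes = paste(c(cl$violations, cl$notes), collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  closeness <- ifelse(out$metric == "tree_distance", -out$value, out$value)
  out <- out[order(out$reaction, -closeness, out$candidate_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
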