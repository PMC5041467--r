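## The three-phase construction driver.
##
## Phase 1 (initial construction): search the taxonomic parent of the input
## organism, gate candidates with nSCI > 1, ascending further if nothing is
## accepted; build and calibrate the first family model.
## Phase 2 (expansion): ascend one taxonomy level per round, excluding the
## previously searched sub-tree; accept hits with model E-value below the
## strict cutoff, park hits below the relaxed cutoff as potential members;
## re-align, recompute the consensus, rebuild and recalibrate after every
## round with new members.
## Phase 3 (finalization): one unrestricted round, re-evaluation of the
## potential members with the strict cutoff under the final model, and a
## final rebuild + calibration.

#' Pipeline configuration
#'
#' @param strict_evalue model E-value below which a hit becomes a member
#'   (strict inequality; default 0.001).
#' @param relaxed_evalue model E-value at or below which a non-member hit is
#'   parked as a potential member (default 1).
#' @param search_evalue E-value cutoff of the similarity search (default 1).
#' @param max_queries queries per search round (default 5).
#' @param use_clustering select queries by UPGMA clustering instead of the
#'   first-five rule.
#' @param filter a [filter_config()].
#' @param database_size database size (nt) for model E-values; mirrors the
#'   genome-size parameter a covariance-model search would use, which the
#'   pipeline sets to the database size of the similarity search.  `NULL`
#'   (the default) derives it from the target collection at run time.
#' @param seed integer seed for every source of randomness in a run.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(strict_evalue = 0.001, relaxed_evalue = 1,
                            search_evalue = 1, max_queries = 5L,
                            use_clustering = FALSE, filter = filter_config(),
                            database_size = NULL, seed = 1L) {
  if (strict_evalue > relaxed_evalue) {
    stop("config error: strict_evalue must be <= relaxed_evalue")
  }
  if (search_evalue > relaxed_evalue) {
    warning("search_evalue exceeds relaxed_evalue; extra hits cannot become members")
  }
  structure(list(strict_evalue = strict_evalue,
                 relaxed_evalue = relaxed_evalue,
                 search_evalue = search_evalue,
                 max_queries = as.integer(max_queries),
                 use_clustering = isTRUE(use_clustering),
                 filter = filter, database_size = database_size,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Default backend set
#'
#' @return list with `folding` (a `folding_backend`), `aligner` (a
#'   `pairwise_aligner`) and `scoring` (a `scoring_scheme`).
#' @export
default_backends <- function() {
  list(folding = fold_backend_default(),
       aligner = align_backend_reference(),
       scoring = scoring_scheme())
}

log_event <- function(state, phase, event, ...) {
  state$log[[length(state$log) + 1L]] <- c(list(n = length(state$log) + 1L,
                                                phase = phase, event = event),
                                           list(...))
  state
}

empty_members <- function() {
  tibble(id = character(), seq = character(), taxid = integer(),
         contig = character(), start = integer(), end = integer(),
         strand = character(), origin = character(), evalue = numeric())
}

member_row <- function(id, seq, taxid, contig = NA_character_,
                       start = NA_integer_, end = NA_integer_,
                       strand = NA_character_, origin, evalue = NA_real_) {
  tibble(id = id, seq = seq, taxid = as.integer(taxid), contig = contig,
         start = as.integer(start), end = as.integer(end), strand = strand,
         origin = origin, evalue = evalue)
}

redundant_with <- function(seq, seqs, threshold) {
  if (length(seqs) == 0L) return(FALSE)
  any(vapply(seqs, function(s) sequence_identity(seq, s), numeric(1)) >= threshold)
}

## Same genomic locus (>= 50% reciprocal overlap on the same contig, either
## strand) as a row already collected.
locus_collected <- function(prov, tbl) {
  if (nrow(tbl) == 0L || is.na(prov$contig)) return(FALSE)
  same <- tbl[!is.na(tbl$contig) & tbl$contig == prov$contig, , drop = FALSE]
  for (k in seq_len(nrow(same))) {
    if (interval_reciprocal_overlap(prov$start, prov$end,
                                    same$start[k], same$end[k]) >= 0.5) {
      return(TRUE)
    }
  }
  FALSE
}

## Merge pairwise (input, candidate) alignments into one multiple alignment
## anchored on the input sequence: candidate residues aligned to the same
## input position share a column; insertions relative to the input are pooled
## per inter-position slot.
merge_pairwise_alignments <- function(input, cands) {
  n <- nchar(input$seq)
  ch_in <- str_chars(input$seq)
  per_cand <- lapply(cands, function(cand) {
    a <- str_chars(cand$alignment$rows[1])   # input row
    b <- str_chars(cand$alignment$rows[2])   # candidate row
    aligned <- rep("-", n)
    inserts <- vector("list", n + 1L)
    for (g in seq_len(n + 1L)) inserts[[g]] <- character(0)
    p <- 0L
    for (k in seq_along(a)) {
      if (is_gap(a[k])) {
        if (!is_gap(b[k])) inserts[[p + 1L]] <- c(inserts[[p + 1L]], b[k])
      } else {
        p <- p + 1L
        if (!is_gap(b[k])) aligned[p] <- b[k]
      }
    }
    list(aligned = aligned, inserts = inserts)
  })
  ins_len <- vapply(seq_len(n + 1L), function(g) {
    if (length(per_cand) == 0L) 0L
    else max(vapply(per_cand, function(pc) length(pc$inserts[[g]]), integer(1)))
  }, integer(1))
  build_row <- function(aligned, inserts) {
    out <- character(0)
    for (g in seq_len(n + 1L)) {
      ins <- inserts[[g]]
      out <- c(out, ins, rep("-", ins_len[g] - length(ins)))
      if (g <= n) out <- c(out, aligned[g])
    }
    paste(out, collapse = "")
  }
  rows <- c(build_row(ch_in, replicate(n + 1L, character(0), simplify = FALSE)),
            vapply(per_cand, function(pc) build_row(pc$aligned, pc$inserts),
                   character(1)))
  ids <- c(input$id, vapply(cands, function(cand) cand$alignment$ids[2], character(1)))
  rna_alignment(ids, rows)
}

rebuild_model <- function(members, alignment, cfg, backends, cal_seed) {
  cons <- backends$folding$fold_alignment(alignment)
  alignment$consensus <- cons$structure
  model <- model_build(alignment)
  model <- model_calibrate(model, seed = cal_seed)
  list(alignment = alignment, model = model)
}

candidate_id <- function(prov) {
  paste0(prov$contig, "/", prov$start, "-", prov$end, "(", prov$strand, ")")
}

#' Initial family construction
#'
#' Searches the taxonomic parent of the input organism with the input as
#' sole query, filters and truncates the hits, and accepts candidates whose
#' nSCI exceeds 1.  If a round accepts nothing the search ascends one
#' taxonomy level and repeats, up to the root.  The accepted sequences and
#' the input are merged into a structural alignment, a consensus structure
#' is computed, and the first family model is built and calibrated.
#'
#' @param input one-row record tibble (the input sequence).
#' @param start_taxon taxon id of the input organism, or `NULL` for a single
#'   global phase starting at the root.
#' @param tree a `taxonomy_tree`.
#' @param targets contig tibble with `taxid` annotations.
#' @param cfg a [pipeline_config()].
#' @param backends backend list, see [default_backends()].
#' @return a `family_state`.
#' @export
initial_construction <- function(input, start_taxon, tree, targets,
                                 cfg = pipeline_config(),
                                 backends = default_backends()) {
  if (!nzchar(input$seq)) stop("input error: empty input sequence")
  state <- structure(list(
    input = input, members = empty_members(), potentials = empty_members(),
    alignment = NULL, model = NULL,
    current = NA_integer_, previous = NULL, iteration = 0L, log = list()
  ), class = "family_state")

  current <- if (is.null(start_taxon) || is.na(start_taxon)) {
    tree$root
  } else {
    parent_of(tree, start_taxon)
  }
  col1 <- function(col, default) if (col %in% names(input)) input[[col]][1] else default
  input_tbl <- member_row(input$id, input$seq, col1("taxid", NA_integer_),
                          col1("contig", NA_character_),
                          col1("start", NA_integer_),
                          col1("end", NA_integer_),
                          col1("strand", NA_character_),
                          origin = "input")
  accepted <- list()
  repeat {
    scope <- scope_for_iteration(tree, current, NULL)
    hits <- search_hits(queries = input, targets = targets, tree = tree,
                        scope = scope, evalue_cutoff = cfg$search_evalue,
                        scoring = backends$scoring,
                        max_queries = cfg$max_queries)
    pre <- prefilter_hits(hits, input, input_tbl, cfg$filter, targets)
    state <- log_event(state, "initial", "search", node = current,
                       n_hits = nrow(hits), n_filtered = nrow(pre))
    batch_seqs <- character(0)
    for (i in seq_len(nrow(pre))) {
      hit <- pre[i, ]
      expanded <- expand_hit(hit, nchar(input$seq), cfg$filter, targets)
      cand <- truncate_to_input(input, expanded, backends$aligner)
      cand <- score_candidate(cand, backends$folding)
      batch_tbl <- if (length(accepted)) {
        bind_rows(lapply(accepted, function(a) {
          tibble(contig = a$provenance$contig, start = a$provenance$start,
                 end = a$provenance$end)
        }))
      } else {
        tibble(contig = character(), start = integer(), end = integer())
      }
      ok <- accept_candidate(cand) &&
        !redundant_with(cand$seq, batch_seqs, cfg$filter$redundancy_identity) &&
        !locus_collected(cand$provenance, batch_tbl)
      state <- log_event(state, "initial", "candidate",
                         id = candidate_id(cand$provenance),
                         si = cand$si, sci = cand$sci, nsci = cand$nsci,
                         accepted = ok)
      if (ok) {
        accepted[[length(accepted) + 1L]] <- cand
        batch_seqs <- c(batch_seqs, cand$seq)
      }
    }
    if (length(accepted) > 0L || current == tree$root) break
    current <- parent_of(tree, current)
    state <- log_event(state, "initial", "ascend", node = current)
  }

  members <- input_tbl
  for (cand in accepted) {
    members <- bind_rows(members, member_row(
      candidate_id(cand$provenance), cand$seq, cand$taxid,
      cand$provenance$contig, cand$provenance$start, cand$provenance$end,
      cand$provenance$strand, origin = "initial"))
  }
  if (length(accepted) == 0L) {
    warning("no candidate accepted up to the root; degenerate single-sequence family")
    state <- log_event(state, "initial", "degenerate-family")
  }
  alignment <- if (length(accepted)) {
    merge_pairwise_alignments(input, accepted)
  } else {
    rna_alignment(input$id, input$seq)
  }
  rebuilt <- rebuild_model(members, alignment, cfg, backends,
                           cal_seed = derive_seed(cfg$seed, 100L))
  state$members <- members
  state$alignment <- rebuilt$alignment
  state$model <- rebuilt$model
  state$current <- current
  state$previous <- NULL
  state <- log_event(state, "initial", "model-built",
                     n_members = nrow(members), node = current)
  state
}

#' One model-expansion round
#'
#' Ascends one taxonomy level (excluding the sub-tree of the previous
#' round), searches with up to `max_queries` representative queries, and
#' evaluates the filtered hits with the current family model: hits with
#' E-value strictly below the strict cutoff join the members, hits at or
#' below the relaxed cutoff are parked as potential members.  When members
#' were added the family is re-aligned to the model, the consensus structure
#' recomputed, and the model rebuilt and recalibrated.  The state advance is
#' all-or-nothing: a backend failure propagates and leaves the input state
#' untouched.
#'
#' @param state a `family_state` with a calibrated model.
#' @param tree,targets,cfg,backends as in [initial_construction()].
#' @return the advanced `family_state`.
#' @export
expansion_iteration <- function(state, tree, targets, cfg = pipeline_config(),
                                backends = default_backends()) {
  stopifnot(inherits(state, "family_state"))
  if (is.null(state$model$calibration)) stop("state error: model is not calibrated")
  nxt <- parent_of(tree, state$current)
  if (nxt == state$current) return(state)   # root reached; nothing to expand
  scope <- scope_for_iteration(tree, nxt, state$current)
  state2 <- expansion_round(state, tree, targets, cfg, backends, scope,
                            phase = "expansion")
  state2$previous <- state2$current
  state2$current <- nxt
  state2$iteration <- state2$iteration + 1L
  state2
}

## Shared search-evaluate-rebuild body of the expansion and final rounds.
expansion_round <- function(state, tree, targets, cfg, backends, scope, phase) {
  members <- state$members
  queries <- if (cfg$use_clustering) {
    select_queries_clustered(members, cfg$max_queries)
  } else {
    select_queries(dedupe_members(members, cfg$filter$query_dedup_identity),
                   cfg$max_queries)
  }
  hits <- search_hits(queries = queries, targets = targets, tree = tree,
                      scope = scope, evalue_cutoff = cfg$search_evalue,
                      scoring = backends$scoring,
                      max_queries = cfg$max_queries)
  pre <- prefilter_hits(hits, state$input, members, cfg$filter, targets)
  state <- log_event(state, phase, "search", node = scope$include,
                     exclude = scope$exclude %||% NA, n_queries = nrow(queries),
                     n_hits = nrow(hits), n_filtered = nrow(pre))
  if (nrow(pre) == 0L) return(state)

  cands <- lapply(seq_len(nrow(pre)), function(i) {
    expanded <- expand_hit(pre[i, ], nchar(state$input$seq), cfg$filter, targets)
    truncate_to_input(state$input, expanded, backends$aligner)
  })
  cand_tbl <- tibble(id = vapply(cands, function(x) candidate_id(x$provenance),
                                 character(1)),
                     seq = vapply(cands, function(x) x$seq, character(1)))
  eval <- model_search(state$model, cand_tbl,
                       cfg$database_size %||% sum(nchar(targets$seq)))

  added <- FALSE
  for (i in seq_len(nrow(eval))) {
    cand <- cands[[i]]
    ev <- eval$evalue[i]
    if (ev < cfg$strict_evalue) {
      if (redundant_with(cand$seq, state$members$seq,
                         cfg$filter$redundancy_identity) ||
          locus_collected(cand$provenance, state$members)) next
      state$members <- bind_rows(state$members, member_row(
        eval$id[i], cand$seq, cand$taxid, cand$provenance$contig,
        cand$provenance$start, cand$provenance$end, cand$provenance$strand,
        origin = phase, evalue = ev))
      added <- TRUE
      state <- log_event(state, phase, "member-accepted", id = eval$id[i],
                         evalue = ev)
    } else if (ev <= cfg$relaxed_evalue) {
      if (redundant_with(cand$seq, c(state$members$seq, state$potentials$seq),
                         cfg$filter$redundancy_identity) ||
          locus_collected(cand$provenance, state$members) ||
          locus_collected(cand$provenance, state$potentials)) next
      state$potentials <- bind_rows(state$potentials, member_row(
        eval$id[i], cand$seq, cand$taxid, cand$provenance$contig,
        cand$provenance$start, cand$provenance$end, cand$provenance$strand,
        origin = paste0(phase, "-potential"), evalue = ev))
      state <- log_event(state, phase, "potential-collected", id = eval$id[i],
                         evalue = ev)
    }
  }
  if (added) {
    aln <- model_align(state$model, state$members)
    rebuilt <- rebuild_model(state$members, aln, cfg, backends,
                             cal_seed = derive_seed(cfg$seed,
                                                    200L + state$iteration))
    state$alignment <- rebuilt$alignment
    state$model <- rebuilt$model
    state <- log_event(state, phase, "model-rebuilt",
                       n_members = nrow(state$members))
  }
  state
}

#' Finalize the family
#'
#' Runs one search round without taxonomic restriction, then re-evaluates
#' the parked potential members with the current model under the strict
#' cutoff (those passing join the members), and performs the final rebuild
#' and calibration.
#'
#' @param state a `family_state` whose expansion has reached the root.
#' @param tree,targets,cfg,backends as in [initial_construction()].
#' @return a `family_result`: members tibble, structural alignment with
#'   consensus, calibrated model, remaining potentials, and the run log.
#' @export
finalize_family <- function(state, tree, targets, cfg = pipeline_config(),
                            backends = default_backends()) {
  stopifnot(inherits(state, "family_state"))
  scope <- scope_for_iteration(tree, tree$root, NULL)
  state <- expansion_round(state, tree, targets, cfg, backends, scope,
                           phase = "final")
  if (nrow(state$potentials) > 0L) {
    eval <- model_search(state$model, state$potentials,
                         cfg$database_size %||% sum(nchar(targets$seq)))
    promote <- which(eval$evalue < cfg$strict_evalue)
    keep <- setdiff(seq_len(nrow(state$potentials)), promote)
    for (i in promote) {
      p <- state$potentials[i, ]
      if (redundant_with(p$seq, state$members$seq,
                         cfg$filter$redundancy_identity) ||
          locus_collected(list(contig = p$contig, start = p$start, end = p$end),
                          state$members)) next
      p$origin <- "potential-promoted"
      p$evalue <- eval$evalue[i]
      state$members <- bind_rows(state$members, p)
      state <- log_event(state, "final", "potential-promoted", id = p$id,
                         evalue = eval$evalue[i])
    }
    state$potentials <- state$potentials[keep, , drop = FALSE]
  }
  aln <- model_align(state$model, state$members)
  rebuilt <- rebuild_model(state$members, aln, cfg, backends,
                           cal_seed = derive_seed(cfg$seed, 300L))
  state$alignment <- rebuilt$alignment
  state$model <- rebuilt$model
  state <- log_event(state, "final", "finalized",
                     n_members = nrow(state$members),
                     n_potentials_remaining = nrow(state$potentials))
  structure(list(members = state$members, alignment = state$alignment,
                 model = state$model, potentials = state$potentials,
                 input_id = state$input$id, log = state$log),
            class = "family_result")
}

#' @export
print.family_result <- function(x, ...) {
  cat("<family_result> ", nrow(x$members), " members, model of ",
      x$model$columns, " columns, ", length(x$log), " log events\n", sep = "")
  invisible(x)
}

write_log_jsonl <- function(log, path) {
  lines <- vapply(log, function(ev) {
    jsonlite::toJSON(ev, auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

model_to_json <- function(model, path) {
  jsonlite::write_json(list(
    columns = model$columns, consensus = model$consensus,
    col_scores = model$col_scores, pair_cols = model$pair_cols,
    pair_bonus = model$pair_bonus,
    calibration = model$calibration,
    provenance = model$provenance
  ), path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Run the full three-phase family construction
#'
#' @param input input sequence: a FASTA path (first record is used) or a
#'   one-row record tibble.
#' @param taxid taxon of origin of the input, or `NULL` for a single global
#'   phase.
#' @param taxonomy taxonomy TSV path or a `taxonomy_tree`.
#' @param targets target contigs: multi-FASTA path (with `taxid=` header
#'   tokens) or a tibble.
#' @param cfg a [pipeline_config()].
#' @param backends backend list, see [default_backends()].
#' @param outdir optional output directory; when given, writes `result.fa`,
#'   `result.stk`, `model.json`, `log.jsonl` and `report.tsv`.
#' @return a `family_result`.
#' @export
run_family_pipeline <- function(input, taxid = NULL, taxonomy, targets,
                                cfg = pipeline_config(),
                                backends = default_backends(),
                                outdir = NULL) {
  tree <- if (inherits(taxonomy, "taxonomy_tree")) taxonomy else load_taxonomy(taxonomy)
  targ <- if (is.character(targets)) read_fasta(targets) else as_tibble(targets)
  inp <- if (is.character(input)) read_fasta(input)[1, ] else as_tibble(input)[1, ]
  if (!is.null(taxid) && !as.character(as.integer(taxid)) %in% names(tree$parent_map)) {
    stop("input error: start taxon ", taxid, " not in taxonomy")
  }
  state <- initial_construction(inp, taxid, tree, targ, cfg, backends)
  while (parent_of(tree, state$current) != state$current) {
    state <- expansion_iteration(state, tree, targ, cfg, backends)
  }
  result <- finalize_family(state, tree, targ, cfg, backends)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(result$members, file.path(outdir, "result.fa"))
    write_stockholm(result$alignment, file.path(outdir, "result.stk"))
    model_to_json(result$model, file.path(outdir, "model.json"))
    write_log_jsonl(result$log, file.path(outdir, "log.jsonl"))
    utils::write.table(
      as.data.frame(result$members[, c("id", "origin", "evalue", "contig",
                                       "start", "end", "strand")]),
      file.path(outdir, "report.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  result
}
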