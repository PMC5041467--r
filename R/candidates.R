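## Candidate processing: coverage/redundancy pre-filters, flanking expansion,
## and truncation of expanded regions to the input length via a semi-global
## pairwise alignment.

#' Candidate filtering configuration
#'
#' @param min_coverage hits must cover strictly more than this fraction of
#'   the query (default 0.80, "more than 80% coverage").
#' @param redundancy_identity hits at or above this identity to the query or
#'   to an existing member are dropped as redundant (default 0.99).
#' @param query_dedup_identity members above this pairwise identity collapse
#'   to their first representative during query selection (default 0.95).
#' @param flank_factor flanking expansion on each side, as a multiple of the
#'   query length (default 1.0).
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_coverage = 0.80, redundancy_identity = 0.99,
                          query_dedup_identity = 0.95, flank_factor = 1.0) {
  stopifnot(min_coverage > 0, min_coverage <= 1,
            redundancy_identity > 0, redundancy_identity <= 1,
            query_dedup_identity > 0, query_dedup_identity <= 1,
            flank_factor >= 0)
  structure(list(min_coverage = min_coverage,
                 redundancy_identity = redundancy_identity,
                 query_dedup_identity = query_dedup_identity,
                 flank_factor = flank_factor),
            class = "filter_config")
}

hit_sequence <- function(hit, targets) {
  contig <- targets[targets$id == hit$contig, , drop = FALSE]
  if (nrow(contig) != 1L) stop("hit references unknown contig: ", hit$contig)
  extract_region(contig[1, ], hit$start, hit$end, hit$strand)$seq
}

#' Pre-filter raw search hits
#'
#' Keeps hits with query coverage strictly greater than `min_coverage` (to
#' exclude short hits) and drops hits whose extracted sequence has identity
#' at or above `redundancy_identity` to the query or to any existing member
#' (to avoid collecting redundant near-copies).  A hit whose interval has at
#' least 50% reciprocal overlap with an existing member's genomic locus is
#' also a duplicate (the same locus re-found on either strand) and is
#' dropped.  Input order is preserved.
#'
#' @param hits hit tibble from [search_hits()].
#' @param query the query record (one-row tibble with `seq`).
#' @param members tibble of current member records (may have zero rows).
#' @param cfg a [filter_config()].
#' @param targets contig tibble the hits refer to.
#' @return the surviving subset of `hits`, order preserved.
#' @export
prefilter_hits <- function(hits, query, members, cfg, targets) {
  if (nrow(hits) == 0L) return(hits)
  keep <- logical(nrow(hits))
  ref_seqs <- c(query$seq, if (nrow(members)) members$seq)
  member_loci <- if (nrow(members) && "contig" %in% names(members)) {
    members[!is.na(members$contig), c("contig", "start", "end"), drop = FALSE]
  } else {
    NULL
  }
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (!(h$coverage > cfg$min_coverage)) next
    if (!is.null(member_loci) && nrow(member_loci) > 0L) {
      same <- member_loci[member_loci$contig == h$contig, , drop = FALSE]
      dup <- FALSE
      for (k in seq_len(nrow(same))) {
        if (interval_reciprocal_overlap(h$start, h$end,
                                        same$start[k], same$end[k]) >= 0.5) {
          dup <- TRUE
          break
        }
      }
      if (dup) next
    }
    hseq <- hit_sequence(h, targets)
    ident <- vapply(ref_seqs, function(r) sequence_identity(hseq, r), numeric(1))
    if (any(ident >= cfg$redundancy_identity)) next
    keep[i] <- TRUE
  }
  hits[keep, , drop = FALSE]
}

#' Expand a hit with flanking genomic regions
#'
#' Search hits are usually shorter than the full element, so the hit interval
#' is widened by `ceil(flank_factor * query_length)` on each side, clipped to
#' the contig bounds, and extracted strand-aware.
#'
#' @param hit one-row hit tibble.
#' @param query_length length of the query sequence.
#' @param cfg a [filter_config()].
#' @param targets contig tibble.
#' @return one-row record tibble with provenance (see [extract_region()]).
#' @export
expand_hit <- function(hit, query_length, cfg, targets) {
  contig <- targets[targets$id == hit$contig, , drop = FALSE]
  if (nrow(contig) != 1L) stop("hit references unknown contig: ", hit$contig)
  f <- ceiling(cfg$flank_factor * query_length)
  s <- max(0L, hit$start - f)
  e <- min(nchar(contig$seq[1]), hit$end + f)
  extract_region(contig[1, ], s, e, hit$strand)
}

#' Reference semi-global pairwise aligner
#'
#' Sequence-based Needleman-Wunsch with free end gaps on the second (longer,
#' genomic-excerpt) sequence: the first sequence is aligned globally, the
#' second locally.  Scoring: match +2, mismatch -1, gap -2 per residue.
#' Stands behind the pairwise structural-aligner contract used for candidate
#' truncation; truncation needs coordinates, structure enters later through
#' the SCI.
#'
#' @return a `pairwise_aligner` object whose `align(a, b)` returns aligned
#'   rows, the score, and the 0-based half-open span of `b` covered by the
#'   alignment.
#' @export
align_backend_reference <- function() {
  submat <- matrix(-1, 5, 5, dimnames = list(VALID_RESIDUES, VALID_RESIDUES))
  diag(submat) <- 2
  submat["N", ] <- 0
  submat[, "N"] <- 0
  align <- function(a, b) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = a, subject = b, type = "global-local",
      substitutionMatrix = submat, gapOpening = 0, gapExtension = 2
    )
    list(
      a_row = as.character(Biostrings::alignedPattern(pa)),
      b_row = as.character(Biostrings::alignedSubject(pa)),
      score = Biostrings::score(pa),
      b_span = c(Biostrings::start(Biostrings::subject(pa)) - 1L,
                 Biostrings::end(Biostrings::subject(pa)))
    )
  }
  structure(list(name = "reference-semiglobal", align = align),
            class = "pairwise_aligner")
}

#' Truncate an expanded region to the input sequence
#'
#' Aligns the input semi-globally against the expanded genomic region (free
#' end gaps on the expanded side) and keeps the expanded subsequence spanned
#' by the alignment as the candidate.  Truncation itself never rejects a
#' candidate; rejection is the job of the nSCI gate or the model E-value.
#'
#' @param input one-row record tibble of the input sequence.
#' @param expanded one-row record tibble from [expand_hit()].
#' @param aligner a `pairwise_aligner`.
#' @return a `candidate` object carrying the truncated sequence, its pairwise
#'   alignment to the input, and genomic provenance.
#' @export
truncate_to_input <- function(input, expanded, aligner = align_backend_reference()) {
  stopifnot(inherits(aligner, "pairwise_aligner"))
  res <- tryCatch(aligner$align(input$seq, expanded$seq),
                  error = function(e) stop("backend error: pairwise aligner failed: ",
                                           conditionMessage(e)))
  s0 <- res$b_span[1]
  e0 <- res$b_span[2]
  cand_seq <- substr(expanded$seq, s0 + 1L, e0)
  ## Map the truncated span back to plus-strand contig coordinates.
  prov <- list(contig = expanded$contig %||% NA_character_,
               start = NA_integer_, end = NA_integer_,
               strand = expanded$strand %||% NA_character_)
  if (!is.null(expanded$start) && !is.na(expanded$start)) {
    if (expanded$strand == "+") {
      prov$start <- expanded$start + s0
      prov$end <- expanded$start + e0
    } else {
      prov$start <- expanded$end - e0
      prov$end <- expanded$end - s0
    }
  }
  aln <- rna_alignment(
    ids = c(input$id, paste0(prov$contig, "/", prov$start, "-", prov$end,
                             "(", prov$strand, ")")),
    rows = c(res$a_row, res$b_row)
  )
  structure(list(seq = cand_seq, input_seq = input$seq, alignment = aln,
                 provenance = prov, taxid = expanded$taxid,
                 si = NA_real_, sci = NA_real_, nsci = NA_real_,
                 scored = FALSE),
            class = "candidate")
}

#' @export
print.candidate <- function(x, ...) {
  cat("<candidate> ", nchar(x$seq), " nt",
      if (isTRUE(x$scored)) sprintf("  SI=%.3f SCI=%.3f nSCI=%.3f", x$si, x$sci, x$nsci),
      "\n", sep = "")
  invisible(x)
}
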