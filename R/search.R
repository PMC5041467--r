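## Local similarity-search backend.
##
## The pipeline contract is BLAST-like: given query sequences, a taxonomic
## scope and an E-value cutoff, return scored hits with subject intervals,
## strand, coverage and subject taxon.  The reference implementation runs a
## best local alignment (Smith-Waterman, affine gaps) of every query against
## every in-scope contig on both strands through Biostrings, and converts
## scores to E-values with Karlin-Altschul statistics under a uniform
## background.  Desk-scale target collections make the exhaustive scan cheap
## and fully deterministic.

#' Scoring scheme for the local search backend
#'
#' BLASTn-like defaults.  A gap of length `k` costs `open + k * extend`.
#'
#' @param match positive match score.
#' @param mismatch mismatch score (negative).
#' @param gap_open gap opening cost (negative).
#' @param gap_extend per-residue gap extension cost (negative).
#' @param K Karlin-Altschul prefactor for E-value estimation.
#' @return a `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = -5,
                           gap_extend = -2, K = 0.1) {
  if (match <= 0) stop("config error: match score must be positive")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, K = K),
            class = "scoring_scheme")
}

substitution_matrix <- function(scoring) {
  m <- matrix(scoring$mismatch, 5, 5,
              dimnames = list(VALID_RESIDUES, VALID_RESIDUES))
  diag(m) <- scoring$match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Karlin-Altschul lambda for a match/mismatch scheme
#'
#' Solves `sum_i sum_j p_i p_j exp(lambda * s_ij) = 1` for `lambda > 0` under
#' a uniform residue background.
#'
#' @param scoring a [scoring_scheme()].
#' @return lambda.
#' @export
karlin_lambda <- function(scoring) {
  expected <- (4 * scoring$match + 12 * scoring$mismatch) / 16
  if (expected >= 0) {
    stop("Karlin-Altschul precondition error: expected score must be negative")
  }
  f <- function(l) (4 * exp(l * scoring$match) +
                      12 * exp(l * scoring$mismatch)) / 16 - 1
  uniroot(f, c(1e-9, 10), tol = 1e-12)$root
}

#' E-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`; linear in the database length and
#' monotone decreasing in the score.
#'
#' @param score alignment score.
#' @param query_length query length `m`.
#' @param database_length database length `n` (total nucleotides searched).
#' @param scoring a [scoring_scheme()].
#' @return E-value.
#' @export
estimate_evalue <- function(score, query_length, database_length,
                            scoring = scoring_scheme()) {
  stopifnot(query_length >= 1, database_length >= query_length)
  lambda <- karlin_lambda(scoring)
  scoring$K * query_length * database_length * exp(-lambda * score)
}

#' Best local alignment of two sequences
#'
#' Smith-Waterman with affine gaps via Biostrings.  Spans are returned
#' 0-based half-open; a best score `<= 0` is reported as score 0 with empty
#' spans (the empty local alignment).
#'
#' @param query,subject residue strings.
#' @param scoring a [scoring_scheme()].
#' @return list with `score`, `query_span`, `subject_span`.
#' @export
local_align_score <- function(query, subject, scoring = scoring_scheme()) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty input to local_align_score")
  pa <- Biostrings::pairwiseAlignment(
    pattern = query, subject = subject, type = "local",
    substitutionMatrix = substitution_matrix(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend
  )
  s <- Biostrings::score(pa)
  if (s <= 0) {
    return(list(score = 0, query_span = c(0L, 0L), subject_span = c(0L, 0L)))
  }
  qs <- Biostrings::start(Biostrings::pattern(pa))
  qe <- Biostrings::end(Biostrings::pattern(pa))
  ss <- Biostrings::start(Biostrings::subject(pa))
  se <- Biostrings::end(Biostrings::subject(pa))
  list(score = s,
       query_span = c(qs - 1L, qe),
       subject_span = c(ss - 1L, se))
}

empty_hits <- function() {
  tibble(query_id = character(), contig = character(),
         start = integer(), end = integer(), strand = character(),
         score = numeric(), evalue = numeric(), coverage = numeric(),
         taxid = integer())
}

#' Similarity search over a taxonomic scope
#'
#' Runs every query against every contig whose taxon lies in the scope, on
#' both strands, keeping the best local alignment per (query, contig, strand)
#' whose E-value passes the cutoff.  Results from all queries are pooled,
#' deduplicated by (contig, interval, strand), and sorted by ascending
#' E-value.
#'
#' @param queries tibble of query records (`id`, `seq`), 1 to `max_queries`
#'   rows.
#' @param targets tibble of annotated contigs (`id`, `seq`, `taxid`).
#' @param tree a `taxonomy_tree`.
#' @param scope a `search_scope`.
#' @param evalue_cutoff maximum E-value of a reported hit.
#' @param scoring a [scoring_scheme()].
#' @param max_queries maximum number of queries allowed per request.
#' @return hit tibble: `query_id`, `contig`, `start`, `end` (0-based
#'   half-open, plus-strand coordinates), `strand`, `score`, `evalue`,
#'   `coverage`, `taxid`.
#' @export
search_hits <- function(queries, targets, tree, scope, evalue_cutoff = 1,
                        scoring = scoring_scheme(), max_queries = 5L) {
  stopifnot(inherits(scope, "search_scope"))
  if (nrow(targets) == 0L) stop("search error: empty target collection")
  if (nrow(queries) < 1L || nrow(queries) > max_queries) {
    stop("search error: number of queries must be in 1..", max_queries)
  }
  if (any(!nzchar(queries$seq))) stop("search error: empty query sequence")
  in_scope <- taxa_in_scope(tree, scope)
  targ <- targets[!is.na(targets$taxid) & targets$taxid %in% in_scope, , drop = FALSE]
  if (nrow(targ) == 0L) return(empty_hits())
  db_len <- sum(nchar(targ$seq))
  lambda <- karlin_lambda(scoring)
  submat <- substitution_matrix(scoring)

  rows <- list()
  for (qi in seq_len(nrow(queries))) {
    q <- queries$seq[qi]
    qlen <- nchar(q)
    for (ti in seq_len(nrow(targ))) {
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") targ$seq[ti] else reverse_complement(targ$seq[ti])
        pa <- Biostrings::pairwiseAlignment(
          pattern = q, subject = subj, type = "local",
          substitutionMatrix = submat,
          gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend
        )
        s <- Biostrings::score(pa)
        if (s <= 0) next
        ev <- scoring$K * qlen * db_len * exp(-lambda * s)
        if (ev > evalue_cutoff) next
        ss <- Biostrings::start(Biostrings::subject(pa)) - 1L  # 0-based
        se <- Biostrings::end(Biostrings::subject(pa))         # half-open
        L <- nchar(subj)
        if (strand == "-") {
          tmp <- ss
          ss <- L - se
          se <- L - tmp
        }
        qspan <- Biostrings::end(Biostrings::pattern(pa)) -
          Biostrings::start(Biostrings::pattern(pa)) + 1L
        rows[[length(rows) + 1L]] <- tibble(
          query_id = queries$id[qi], contig = targ$id[ti],
          start = as.integer(ss), end = as.integer(se), strand = strand,
          score = s, evalue = ev, coverage = qspan / qlen,
          taxid = targ$taxid[ti]
        )
      }
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  hits <- bind_rows(rows)
  hits <- hits[!duplicated(hits[, c("contig", "start", "end", "strand")]), , drop = FALSE]
  hits[order(hits$evalue, hits$contig, hits$start), , drop = FALSE]
}

#' Serialize hits to BLAST-tabular-like TSV
#'
#' Columns follow the familiar tabular layout (`qseqid sseqid pident length
#' evalue bitscore sstart send`); coordinates are 1-based inclusive and a
#' minus-strand hit is encoded by reversed subject coordinates.
#'
#' @param hits hit tibble from [search_hits()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  sstart <- ifelse(hits$strand == "+", hits$start + 1L, hits$end)
  send <- ifelse(hits$strand == "+", hits$end, hits$start + 1L)
  out <- data.frame(qseqid = hits$query_id, sseqid = hits$contig,
                    pident = round(100 * hits$coverage, 2),
                    length = hits$end - hits$start,
                    evalue = signif(hits$evalue, 4), bitscore = hits$score,
                    sstart = sstart, send = send)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
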