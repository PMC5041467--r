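## Candidate-gating statistics.
##
## SI  = 1 - D/L        sequence identity from the Levenshtein distance D and
##                      the length L of the longer sequence.
## SCI = E_cons / mean(E_x)   structure conservation index: consensus folding
##                      energy of the alignment over the mean energy of its
##                      individually folded rows.
## nSCI = SCI / SI      SCI normalized by sequence identity; alignments of
##                      identical sequences necessarily have SCI = 1, so
##                      structure conservation in excess of sequence identity
##                      shows up as nSCI > 1, which is the acceptance gate.

#' Levenshtein distance between two residue strings
#'
#' Unit costs for substitution, insertion and deletion.
#'
#' @param a,b character strings (may be empty).
#' @return integer edit distance.
#' @export
levenshtein <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  as.integer(utils::adist(a, b)[1, 1])
}

#' Sequence identity SI
#'
#' `SI = 1 - D/L` with `D` the Levenshtein distance and `L` the length of the
#' longer of the two (unaligned, gap-free) sequences.
#'
#' @param a,b residue strings; at least one must be non-empty.
#' @return identity in `[0, 1]`.
#' @export
sequence_identity <- function(a, b) {
  L <- max(nchar(a), nchar(b))
  if (L == 0L) stop("undefined: sequence identity of two empty strings")
  1 - levenshtein(a, b) / L
}

#' Structure conservation index SCI
#'
#' Ratio of the consensus folding energy of an alignment to the mean folding
#' energy of its individual (ungapped) rows.  When none of the rows folds
#' (mean single-sequence energy 0) the SCI is 0 by convention.
#'
#' @param aln an `rna_alignment` with at least 2 rows.
#' @param backend a `folding_backend`; default [fold_backend_default()].
#' @return non-negative SCI value.
#' @export
sci <- function(aln, backend = fold_backend_default()) {
  stopifnot(inherits(aln, "rna_alignment"), inherits(backend, "folding_backend"))
  if (length(aln$rows) < 2L) stop("SCI needs an alignment with >= 2 rows")
  singles <- vapply(aln$rows, function(r) backend$fold(ungap(r))$energy, numeric(1))
  denom <- mean(singles)
  if (denom == 0) return(0)
  consensus_fold <- backend$fold_alignment_sci %||% backend$fold_alignment
  consensus_fold(aln)$energy / denom
}

#' Normalized structure conservation index nSCI
#'
#' `nSCI = SCI / SI`.  For `SI = 0` the value is defined as 0 (the candidate
#' cannot pass the acceptance gate) rather than an error.
#'
#' @param si sequence identity in `[0, 1]`.
#' @param sci structure conservation index.
#' @return nSCI value.
#' @export
nsci <- function(si, sci) {
  stopifnot(si >= 0, si <= 1)
  if (si == 0) return(0)
  sci / si
}

#' Score a candidate against the input sequence
#'
#' Computes the full score triple (SI on the unaligned sequences, SCI on the
#' pairwise alignment, nSCI) and stores it on the candidate.
#'
#' @param cand a `candidate` object from [truncate_to_input()].
#' @param backend a `folding_backend`.
#' @return the candidate with `si`, `sci`, `nsci` populated.
#' @export
score_candidate <- function(cand, backend = fold_backend_default()) {
  stopifnot(inherits(cand, "candidate"))
  cand$si <- sequence_identity(cand$input_seq, cand$seq)
  cand$sci <- sci(cand$alignment, backend)
  cand$nsci <- nsci(cand$si, cand$sci)
  cand$scored <- TRUE
  cand
}

#' Candidate acceptance gate
#'
#' A scored candidate is accepted into the initial family if and only if its
#' nSCI is strictly greater than 1.
#'
#' @param cand a scored `candidate`.
#' @return logical.
#' @export
accept_candidate <- function(cand) {
  stopifnot(inherits(cand, "candidate"))
  if (!isTRUE(cand$scored)) stop("state error: candidate has not been scored")
  cand$nsci > 1
}
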