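## Consensus-structure comparison and recovery accounting.
##
## Two consensus structures are comparable once both are projected onto a
## sequence they share (the pipeline input): alignment columns where the
## shared sequence has a gap are removed, and any base pair that loses one
## endpoint this way is set to unpaired.  The base-pair distance between the
## projections (symmetric difference of the pair sets) is normalized by the
## ungapped length of the shared sequence.

#' Project a consensus structure onto one ungapped row
#'
#' @param row gapped alignment row of the shared sequence.
#' @param consensus dot-bracket consensus over the alignment columns, same
#'   width as `row`.
#' @return dot-bracket string over the ungapped row; pairs with exactly one
#'   endpoint in a dropped column become unpaired.
#' @export
project_structure <- function(row, consensus) {
  if (nchar(row) != nchar(consensus)) {
    stop("invariant error: row and consensus have different lengths")
  }
  rc <- str_chars(row)
  keep <- !is_gap(rc)
  newpos <- cumsum(keep)                     # column -> position in projection
  pairs <- dotbracket_pairs(consensus)
  n <- sum(keep)
  if (nrow(pairs) == 0L) return(paste(rep(".", n), collapse = ""))
  ok <- keep[pairs[, 1]] & keep[pairs[, 2]]
  kept <- pairs[ok, , drop = FALSE]
  pairs_to_dotbracket(cbind(newpos[kept[, 1]], newpos[kept[, 2]]), n)
}

#' Base-pair distance between two equal-length structures
#'
#' The cardinality of the symmetric difference of the two base-pair sets:
#' zero iff the pair sets are equal, and symmetric in its arguments.
#'
#' @param s1,s2 dot-bracket strings of equal length.
#' @return integer distance.
#' @export
basepair_distance <- function(s1, s2) {
  if (nchar(s1) != nchar(s2)) {
    stop("error: structures have different lengths (", nchar(s1), " vs ",
         nchar(s2), ")")
  }
  key <- function(db) {
    p <- dotbracket_pairs(db)
    if (nrow(p) == 0L) character(0) else paste(p[, 1], p[, 2], sep = ":")
  }
  k1 <- key(s1)
  k2 <- key(s2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Length-normalized structure distance between two alignments
#'
#' Projects the consensus structure of each alignment onto the row of the
#' shared sequence and divides the base-pair distance of the projections by
#' the ungapped length of that sequence.
#'
#' @param aln_a,aln_b `rna_alignment`s with consensus, both containing a row
#'   with id `shared_id`.
#' @param shared_id id of the shared (input) sequence.
#' @return normalized distance (non-negative float).
#' @export
normalized_structure_distance <- function(aln_a, aln_b, shared_id) {
  get_row <- function(aln) {
    ix <- match(shared_id, aln$ids)
    if (is.na(ix)) stop("error: shared id '", shared_id, "' missing from alignment")
    if (is.null(aln$consensus)) stop("error: alignment has no consensus structure")
    aln$rows[ix]
  }
  ra <- get_row(aln_a)
  rb <- get_row(aln_b)
  pa <- project_structure(ra, aln_a$consensus)
  pb <- project_structure(rb, aln_b$consensus)
  if (nchar(pa) != nchar(pb)) {
    stop("error: shared sequence has different ungapped lengths in the two alignments")
  }
  basepair_distance(pa, pb) / nchar(pa)
}

interval_reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- max(0L, min(e1, e2) - max(s1, s2))
  if (ov == 0L) return(0)
  min(ov / (e1 - s1), ov / (e2 - s2))
}

#' Recovery report against a planted truth table
#'
#' A reported member counts as true when its genomic provenance interval has
#' at least `min_overlap` reciprocal overlap with a planted interval on the
#' same contig.  Recall is true-found over planted; specificity is
#' true-found over reported.
#'
#' @param members tibble of reported members with `contig`, `start`, `end`,
#'   `strand` provenance columns (rows with `NA` provenance are skipped).
#' @param truth truth tibble with `contig`, `start`, `end`, `strand` (one
#'   row per planted instance, `taxid` recommended).
#' @param min_overlap reciprocal-overlap threshold (default 0.5).
#' @return a `recovery_report`: list with `recall`, `specificity`, and the
#'   per-member `assignments` tibble.
#' @export
recovery_report <- function(members, truth, min_overlap = 0.5) {
  if (nrow(truth) == 0L) stop("undefined recall: empty truth table")
  memb <- members[!is.na(members$contig), , drop = FALSE]
  matched_truth <- rep(NA_integer_, nrow(memb))
  for (i in seq_len(nrow(memb))) {
    same <- which(truth$contig == memb$contig[i])
    for (t in same) {
      ro <- interval_reciprocal_overlap(memb$start[i], memb$end[i],
                                        truth$start[t], truth$end[t])
      if (ro >= min_overlap) {
        matched_truth[i] <- t
        break
      }
    }
  }
  truth_recovered <- length(unique(matched_truth[!is.na(matched_truth)]))
  true_members <- sum(!is.na(matched_truth))
  reported <- nrow(memb)
  assignments <- tibble(
    member_id = memb$id,
    contig = memb$contig, start = memb$start, end = memb$end,
    strand = memb$strand,
    matched_truth = ifelse(is.na(matched_truth), NA_character_,
                           paste0(truth$contig[matched_truth], ":",
                                  truth$start[matched_truth], "-",
                                  truth$end[matched_truth]))
  )
  structure(list(
    recall = truth_recovered / nrow(truth),
    specificity = if (reported == 0L) 1 else true_members / reported,
    n_planted = nrow(truth), n_reported = reported,
    n_true = truth_recovered, n_true_members = true_members,
    assignments = assignments
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> recall %.3f (%d/%d planted), specificity %.3f (%d/%d reported)\n",
              x$recall, x$n_true, x$n_planted, x$specificity,
              x$n_true_members, x$n_reported))
  invisible(x)
}

#' Write the evaluation report TSV
#'
#' One row per reported member: id, matched truth interval (or NA),
#' provenance; distances are printed to 6 decimals by the callers that add
#' them.
#'
#' @param report a `recovery_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path) {
  utils::write.table(as.data.frame(report$assignments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
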