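## Sequence and alignment I/O.
##
## Sequence sets are tibbles with columns id, description, seq, taxid and
## optional provenance columns (contig, start, end, strand); coordinates are
## 0-based half-open everywhere inside the package.  DNA input is mapped to
## the RNA alphabet (T -> U) on read because all folding backends operate on
## RNA.

VALID_RESIDUES <- c("A", "C", "G", "U", "N")

normalize_residues <- function(x, where = "sequence") {
  x <- chartr("t", "u", chartr("T", "U", x))
  x <- toupper(x)
  bad <- gsub("[ACGUN]", "", x)
  if (any(nchar(bad) > 0)) {
    stop("parse error in ", where, ": illegal residue(s) '",
         substr(bad[nchar(bad) > 0][1], 1, 5), "'")
  }
  x
}

parse_taxid_token <- function(desc) {
  m <- regexpr("taxid=[0-9]+", desc)
  out <- rep(NA_integer_, length(desc))
  hit <- m > 0
  out[hit] <- as.integer(sub("taxid=", "", regmatches(desc, m)))
  out
}

#' Read an RNA FASTA file
#'
#' Residues are normalized to the RNA alphabet (`T` is read as `U`); a
#' `taxid=<integer>` token anywhere in the header is parsed into the `taxid`
#' column.
#'
#' @param path path to a (multi-)FASTA file.
#' @return tibble with columns `id`, `description`, `seq`, `taxid`, in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("input error: empty FASTA file: ", path)
  full <- names(set)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  seqs <- normalize_residues(as.character(set), where = paste0("FASTA record ", id))
  if (any(!nzchar(seqs))) stop("input error: empty sequence in ", path)
  tibble(id = unname(id), description = unname(desc),
         seq = unname(seqs), taxid = parse_taxid_token(full))
}

#' Write sequence records to FASTA
#'
#' @param records tibble with at least `id` and `seq`; a non-`NA` `taxid`
#'   column is emitted as a `taxid=` header token.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  hdr <- records$id
  if ("taxid" %in% names(records)) {
    tx <- records$taxid
    hdr <- ifelse(!is.na(tx), paste0(hdr, " taxid=", tx), hdr)
  }
  set <- Biostrings::BStringSet(setNames(records$seq, hdr))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a multiple alignment object
#'
#' @param ids character vector of row ids.
#' @param rows character vector of gapped strings, same length as `ids`, all
#'   of identical width.
#' @param consensus optional dot-bracket consensus structure over the
#'   alignment columns (`#=GC SS_cons` in Stockholm output).
#' @return an `rna_alignment` object.
#' @export
rna_alignment <- function(ids, rows, consensus = NULL) {
  stopifnot(length(ids) == length(rows), length(rows) >= 1L)
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("invariant error: alignment rows have unequal length")
  if (!is.null(consensus)) {
    if (nchar(consensus) != w) stop("invariant error: consensus length != alignment width")
    if (!is_balanced_dotbracket(consensus)) stop("invariant error: consensus not balanced")
  }
  structure(list(ids = as.character(ids), rows = as.character(rows),
                 width = w, consensus = consensus),
            class = "rna_alignment")
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat("<rna_alignment> ", length(x$rows), " rows x ", x$width, " columns",
      if (!is.null(x$consensus)) " (+SS_cons)", "\n", sep = "")
  invisible(x)
}

#' Number of rows/columns of an alignment
#' @param aln an `rna_alignment`.
#' @return integer.
#' @export
alignment_ncol <- function(aln) aln$width

#' Write an alignment in Stockholm 1.0 format
#'
#' The consensus structure, when present, is written as a `#=GC SS_cons`
#' line in dot-bracket notation.
#'
#' @param aln an `rna_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(aln, path) {
  stopifnot(inherits(aln, "rna_alignment"))
  name_w <- max(nchar(aln$ids), nchar("#=GC SS_cons"))
  lines <- c("# STOCKHOLM 1.0",
             sprintf("%-*s %s", name_w, aln$ids, aln$rows))
  if (!is.null(aln$consensus)) {
    lines <- c(lines, sprintf("%-*s %s", name_w, "#=GC SS_cons", aln$consensus))
  }
  writeLines(c(lines, "//"), path)
  invisible(path)
}

#' Read a Stockholm 1.0 alignment
#'
#' Supports single-block and interleaved files; `#=GC SS_cons` is parsed into
#' the consensus slot, other annotation lines are ignored.
#'
#' @param path path to a Stockholm file.
#' @return an `rna_alignment`.
#' @export
read_stockholm <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^# STOCKHOLM", lines[1])) {
    stop("parse error: not a Stockholm file: ", path)
  }
  rows <- list()
  order <- character(0)
  ss <- ""
  for (ln in lines[-1]) {
    if (grepl("^//", ln) || !nzchar(trimws(ln))) next
    if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
      ss <- paste0(ss, sub("^#=GC\\s+SS_cons\\s+", "", ln))
      next
    }
    if (grepl("^#", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) stop("parse error: malformed Stockholm row: ", ln)
    if (!parts[1] %in% order) order <- c(order, parts[1])
    rows[[parts[1]]] <- paste0(rows[[parts[1]]] %||% "", parts[2])
  }
  if (length(rows) == 0L) stop("parse error: Stockholm file has no sequence rows")
  rna_alignment(order, unlist(rows[order], use.names = FALSE),
                consensus = if (nzchar(ss)) ss else NULL)
}

#' Extract a genomic sub-region as an RNA sequence record
#'
#' Coordinates are 0-based, half-open.  On the minus strand the extracted
#' substring is reverse-complemented; provenance (contig, interval, strand)
#' is recorded on the returned record.
#'
#' @param contig one-row tibble (or list) with `id` and `seq`.
#' @param start,end 0-based half-open interval on the plus strand.
#' @param strand `"+"` or `"-"`.
#' @return one-row tibble with `id`, `description`, `seq`, `taxid`, `contig`,
#'   `start`, `end`, `strand`.
#' @export
extract_region <- function(contig, start, end, strand = "+") {
  L <- nchar(contig$seq)
  if (!(start >= 0 && start < end && end <= L)) {
    stop("bounds error: interval [", start, ",", end, ") not within contig of length ", L)
  }
  stopifnot(strand %in% c("+", "-"))
  s <- substr(contig$seq, start + 1L, end)
  if (strand == "-") s <- reverse_complement(s)
  tibble(
    id = paste0(contig$id, "/", start, "-", end, "(", strand, ")"),
    description = "",
    seq = s,
    taxid = if ("taxid" %in% names(contig)) contig$taxid else NA_integer_,
    contig = contig$id, start = as.integer(start), end = as.integer(end),
    strand = strand
  )
}
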