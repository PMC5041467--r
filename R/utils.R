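## Internal helpers shared across modules.

RNA_ALPHABET <- c("A", "C", "G", "U")

## Watson-Crick + wobble pairs, used both by the folding backends and the
## family-model pair bonus.
PAIRABLE <- matrix(FALSE, 4, 4, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
PAIRABLE["A", "U"] <- PAIRABLE["U", "A"] <- TRUE
PAIRABLE["G", "C"] <- PAIRABLE["C", "G"] <- TRUE
PAIRABLE["G", "U"] <- PAIRABLE["U", "G"] <- TRUE

can_pair <- function(a, b) {
  ok <- a %in% RNA_ALPHABET & b %in% RNA_ALPHABET
  res <- logical(length(a))
  res[ok] <- PAIRABLE[cbind(a[ok], b[ok])]
  res
}

#' Reverse complement of an RNA string
#'
#' `N` is preserved; the alphabet is `A/C/G/U/N`.
#'
#' @param x a single RNA string.
#' @return the reverse complement string.
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGUN", "UGCAN", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

## Split a string into a character vector of single residues.
str_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_gap <- function(ch) ch %in% c("-", ".", "_", "~")

ungap <- function(x) gsub("[-._~]", "", x)

#' Base pairs of a dot-bracket string
#'
#' @param db dot-bracket string over `(`, `)`, `.` (and gap symbols, treated
#'   as unpaired).
#' @return integer matrix with columns `i`, `j` (1-based, `i < j`), one row
#'   per pair, ordered by `i`.
#' @export
dotbracket_pairs <- function(db) {
  ch <- str_chars(db)
  open <- integer(0)
  ii <- integer(0)
  jj <- integer(0)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      open <- c(open, k)
    } else if (ch[k] == ")") {
      if (length(open) == 0L) stop("unbalanced dot-bracket string: unmatched ')'")
      ii <- c(ii, open[length(open)])
      jj <- c(jj, k)
      open <- open[-length(open)]
    }
  }
  if (length(open) > 0L) stop("unbalanced dot-bracket string: unmatched '('")
  m <- cbind(i = ii, j = jj)
  m[order(m[, "i"]), , drop = FALSE]
}

#' Dot-bracket string from a set of base pairs
#'
#' @param pairs two-column matrix of 1-based pair indices.
#' @param n structure length.
#' @return dot-bracket string of length `n`.
#' @export
pairs_to_dotbracket <- function(pairs, n) {
  ch <- rep(".", n)
  if (length(pairs)) {
    ch[pairs[, 1]] <- "("
    ch[pairs[, 2]] <- ")"
  }
  paste(ch, collapse = "")
}

is_balanced_dotbracket <- function(db) {
  !inherits(tryCatch(dotbracket_pairs(db), error = function(e) e), "error")
}

## Deterministic child seed derivation; keeps derived seeds in 32-bit range.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 31L + 17L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
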