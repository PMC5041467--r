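## Folding backends.
##
## A folding backend is a list with class "folding_backend" providing
##   fold(seq)            -> list(structure = dot-bracket, energy = float)
##   fold_alignment(aln)  -> list(structure = dot-bracket over columns, energy)
## Energies follow a stability-magnitude convention: non-negative, 0 when
## nothing folds.  Thermodynamic backends convert the sign of the MFE at the
## adapter so that SCI is always a ratio of non-negative numbers.

MIN_LOOP <- 3L  # minimum hairpin loop length (unpaired residues between i and j)

## Maximum base-pair count (Nussinov-style) DP over an arbitrary pairability
## predicate given as an n x n logical matrix.  Returns pair matrix + count.
max_pairing <- function(pairable_mat) {
  n <- nrow(pairable_mat)
  M <- matrix(0L, n, n)
  if (n >= MIN_LOOP + 2L) {
    for (span in (MIN_LOOP + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- M[i, j - 1L]
        ks <- i:(j - MIN_LOOP - 1L)
        ks <- ks[pairable_mat[ks, j]]
        if (length(ks)) {
          left <- integer(length(ks))      # M[i, k-1] for k > i, else 0
          sel <- ks > i
          if (any(sel)) left[sel] <- M[cbind(rep(i, sum(sel)), ks[sel] - 1L)]
          inner <- integer(length(ks))     # M[k+1, j-1] when non-empty
          sel2 <- ks + 1L <= j - 1L
          if (any(sel2)) inner[sel2] <- M[cbind(ks[sel2] + 1L, rep(j - 1L, sum(sel2)))]
          best <- max(best, max(left + 1L + inner))
        }
        M[i, j] <- best
      }
    }
  }
  ## Traceback.
  pairs_i <- integer(0); pairs_j <- integer(0)
  if (n >= 2L) {
    stack <- list(c(1L, n))
    while (length(stack)) {
      ij <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- ij[1]; j <- ij[2]
      if (j - i <= MIN_LOOP) next
      if (M[i, j] == M[i, j - 1L]) {
        stack[[length(stack) + 1L]] <- c(i, j - 1L)
        next
      }
      for (k in i:(j - MIN_LOOP - 1L)) {
        if (!pairable_mat[k, j]) next
        left <- if (k > i) M[i, k - 1L] else 0L
        inner <- if (k + 1L <= j - 1L) M[k + 1L, j - 1L] else 0L
        if (left + 1L + inner == M[i, j]) {
          pairs_i <- c(pairs_i, k); pairs_j <- c(pairs_j, j)
          if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
          if (k + 1L <= j - 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
          break
        }
      }
    }
  }
  list(pairs = cbind(i = pairs_i, j = pairs_j), count = if (n) M[1, n] else 0L)
}

#' Reference folding backend (maximum base-pair count)
#'
#' A dependency-free stand-in for a thermodynamic folding engine: the energy
#' of a sequence is its maximum number of nested Watson-Crick/wobble pairs
#' with a minimum hairpin loop of 3, and the consensus energy of an alignment
#' counts a column pair only when every row can pair there (columns containing
#' gaps are excluded from pairing).  Exactly checkable, used throughout the
#' test suite.
#'
#' @return a `folding_backend` object.
#' @export
fold_backend_nussinov <- function() {
  fold <- function(seq) {
    if (!nzchar(seq)) stop("fold error: empty sequence")
    ch <- str_chars(seq)
    n <- length(ch)
    pm <- outer(seq_len(n), seq_len(n),
                function(i, j) can_pair(ch[i], ch[j]))
    res <- max_pairing(pm)
    list(structure = pairs_to_dotbracket(res$pairs, n),
         energy = as.numeric(res$count))
  }
  fold_alignment <- function(aln) {
    stopifnot(inherits(aln, "rna_alignment"))
    mat <- do.call(rbind, lapply(aln$rows, str_chars))
    n <- ncol(mat)
    gapcol <- apply(mat, 2, function(col) any(is_gap(col)))
    pm <- matrix(FALSE, n, n)
    ok <- which(!gapcol)
    for (i in ok) {
      for (j in ok[ok > i]) {
        pm[i, j] <- all(can_pair(mat[, i], mat[, j]))
      }
    }
    res <- max_pairing(pm)
    list(structure = pairs_to_dotbracket(res$pairs, n),
         energy = as.numeric(res$count))
  }
  structure(list(name = "nussinov", fold = fold, fold_alignment = fold_alignment),
            class = "folding_backend")
}

run_tool <- function(cmd, args, input = NULL) {
  out <- suppressWarnings(system2(cmd, args, stdout = TRUE, stderr = FALSE,
                                  input = input))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) stop("backend error: ", cmd, " exited with status ", status)
  out
}

#' ViennaRNA folding backend
#'
#' Adapter over the `RNAfold` / `RNAalifold` command-line tools.
#' Minimum-free-energy values are converted to stability magnitudes
#' (`max(0, -MFE)`), so unstructured inputs get energy 0.
#'
#' The backend distinguishes the two alignment-folding uses of the pipeline:
#' `fold_alignment()` predicts the family consensus structure with RIBOSUM
#' scoring and the covariance weights recommended for consensus structure
#' prediction (`--cfactor 0.6 --nfactor 0.5`), while `fold_alignment_sci()`
#' computes the consensus energy entering the SCI with default RNAalifold
#' scoring, as the RNA gene finder that introduced the SCI does.  The
#' default scoring penalizes inconsistent pairs strongly, which is what
#' makes the SCI collapse for alignments without conserved structure.
#'
#' @return a `folding_backend` object.
#' @export
fold_backend_vienna <- function() {
  if (!nzchar(Sys.which("RNAfold")) || !nzchar(Sys.which("RNAalifold"))) {
    stop("backend error: RNAfold/RNAalifold not found on PATH")
  }
  fold <- function(seq) {
    if (!nzchar(seq)) stop("fold error: empty sequence")
    out <- run_tool("RNAfold", c("--noPS"), input = seq)
    line <- out[length(out)]
    m <- regmatches(line, regexec("^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\s*\\)", line))[[1]]
    if (length(m) != 3L) stop("backend error: cannot parse RNAfold output: ", line)
    list(structure = m[2], energy = max(0, -as.numeric(m[3])))
  }
  alifold <- function(aln, flags) {
    stopifnot(inherits(aln, "rna_alignment"))
    tmp <- tempfile(fileext = ".aln")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(c("CLUSTAL W", "",
                 sprintf("%-20s %s", substr(aln$ids, 1, 18), chartr(".", "-", aln$rows))),
               tmp)
    out <- run_tool("RNAalifold", c("--noPS", flags, tmp))
    line <- out[grepl("^[().,]+\\s+\\(", out)][1]
    if (is.na(line)) stop("backend error: cannot parse RNAalifold output")
    m <- regmatches(line, regexec("^([().,]+)\\s+\\(\\s*(-?[0-9.]+)", line))[[1]]
    if (length(m) != 3L) stop("backend error: cannot parse RNAalifold output: ", line)
    list(structure = chartr(",", ".", m[2]), energy = max(0, -as.numeric(m[3])))
  }
  structure(list(
    name = "vienna",
    fold = fold,
    fold_alignment = function(aln) {
      alifold(aln, c("-r", "--cfactor", "0.6", "--nfactor", "0.5"))
    },
    fold_alignment_sci = function(aln) alifold(aln, character(0))
  ), class = "folding_backend")
}

#' Default folding backend
#'
#' The ViennaRNA adapter when its binaries are available, otherwise the
#' reference maximum-pairing backend.
#'
#' @return a `folding_backend` object.
#' @export
fold_backend_default <- function() {
  if (nzchar(Sys.which("RNAfold")) && nzchar(Sys.which("RNAalifold"))) {
    fold_backend_vienna()
  } else {
    fold_backend_nussinov()
  }
}
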