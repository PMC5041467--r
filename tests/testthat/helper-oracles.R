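## Independent brute-force oracles and fixture builders used across tests.
## Each oracle is written against the definition, not against the package
## implementation it checks.

## -- Levenshtein oracle: plain row-wise DP with unit costs --------------------
oracle_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L,
                         cur[j] + 1L,
                         prev[j] + (ca[i] != cb[j]))
    }
    prev <- cur
  }
  prev[m + 1L]
}

## -- local alignment oracle: explicit affine-gap Smith-Waterman ---------------
## Gap of length k costs open + k * extend (both positive here).
oracle_sw_score <- function(a, b, match = 2, mismatch = -3, open = 5, extend = 2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  NEG <- -1e9
  M <- matrix(0, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consumes b)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - extend, X[i, j + 1L] - extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - extend, Y[i + 1L, j] - extend)
      M[i + 1L, j + 1L] <- max(0,
                               s + max(M[i, j], X[i, j], Y[i, j]))
      best <- max(best, M[i + 1L, j + 1L])
    }
  }
  best
}

## -- taxonomy oracles ---------------------------------------------------------
## Random rooted tree as a node table; node 1 is the root.
random_tree_table <- function(n, seed) {
  set.seed(seed)
  parent <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  tibble::tibble(taxid = seq_len(n), parent = parent,
                 rank = "clade", name = paste0("n", seq_len(n)))
}

## All descendants of `node` (inclusive) by naive repeated scanning.
oracle_descendants <- function(tbl, node) {
  out <- node
  repeat {
    more <- tbl$taxid[tbl$parent %in% out & !(tbl$taxid %in% out)]
    if (length(more) == 0L) break
    out <- c(out, more)
  }
  sort(out)
}

## -- structure oracles --------------------------------------------------------
## Random balanced dot-bracket built by shuffling a valid bracket sequence.
random_dotbracket <- function(n, n_pairs = NULL) {
  if (is.null(n_pairs)) n_pairs <- sample(0:floor(n / 2), 1)
  ch <- rep(".", n)
  avail <- seq_len(n)
  made <- 0L
  while (made < n_pairs && length(avail) >= 2L) {
    ij <- sort(sample(avail, 2))
    ## keep non-crossing: only accept if no existing pair crosses (i, j)
    ok <- TRUE
    if (made > 0L) {
      op <- which(ch == "(")
      cl <- which(ch == ")")
      for (k in seq_along(op)) {
        crosses <- (op[k] < ij[1] && ij[1] < cl[k] && cl[k] < ij[2]) ||
          (ij[1] < op[k] && op[k] < ij[2] && ij[2] < cl[k])
        if (crosses) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      ch[ij[1]] <- "("
      ch[ij[2]] <- ")"
      avail <- setdiff(avail, ij)
      made <- made + 1L
    } else {
      avail <- setdiff(avail, ij)  # give up on this pair of slots
    }
  }
  paste(ch, collapse = "")
}

## Pair set as a logical n x n matrix; distance = positions that disagree.
oracle_bp_distance <- function(s1, s2) {
  pairmat <- function(db) {
    ch <- strsplit(db, "")[[1]]
    n <- length(ch)
    m <- matrix(FALSE, n, n)
    stack <- integer(0)
    for (k in seq_len(n)) {
      if (ch[k] == "(") stack <- c(stack, k)
      if (ch[k] == ")") {
        m[stack[length(stack)], k] <- TRUE
        stack <- stack[-length(stack)]
      }
    }
    m
  }
  sum(xor(pairmat(s1), pairmat(s2)))
}

## -- misc ---------------------------------------------------------------------
random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

dinucleotide_counts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}

## Small shared taxonomy used in several tests:
##   1 -- 2 (Enterobacteriaceae) -- 4 (Enterobacter) -- 6 (E. cloacae)
##                               \- 5 (Escherichia)  -- 7 (E. coli)
toy_taxonomy <- function() {
  taxonomy_tree(tibble::tibble(
    taxid = 1:7,
    parent = c(1L, 1L, 1L, 2L, 2L, 4L, 5L),
    rank = c("root", "family", "family", "genus", "genus", "species", "species"),
    name = c("root", "Enterobacteriaceae", "otherFam", "Enterobacter",
             "Escherichia", "E.cloacae", "E.coli")
  ))
}
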