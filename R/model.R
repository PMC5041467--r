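## Family-model backend.
##
## The reference family model is a profile-with-pair-bonus scorer standing
## behind the covariance-model contract (build / calibrate / search / align):
## per-column nucleotide log-odds capture sequence conservation, and each
## consensus base pair contributes a covariance bonus when the aligned
## residues can pair.  Scores are in bits.  E-values come from a Gumbel null
## fitted to scores of sampled background sequences, scaled by the caller's
## database size -- mirroring the genome-size parameter a covariance-model
## search would use.

GAP_OPEN_BITS <- 4
GAP_EXT_BITS <- 1
EULER_GAMMA <- 0.5772156649015329

res_index <- function(chars) match(chars, RNA_ALPHABET)  # N/gap -> NA

#' Build a family model from a structural alignment
#'
#' Column scores are smoothed log-odds (pseudocount 0.5 per nucleotide) of
#' the column composition against a uniform background.  For every consensus
#' base pair, a covariance bonus is the log-odds of observing complementary
#' (Watson-Crick or G-U) residue pairs across the rows against independence
#' of the two column compositions.
#'
#' @param aln an `rna_alignment` whose `consensus` slot holds the (balanced)
#'   consensus structure.
#' @return a `family_model` (uncalibrated).
#' @export
model_build <- function(aln) {
  stopifnot(inherits(aln, "rna_alignment"))
  if (is.null(aln$consensus)) stop("build error: alignment has no consensus structure")
  ## Identical rows are collapsed before counting (effective-sequence
  ## weighting): replicating a row must not sharpen the model.
  mat <- do.call(rbind, lapply(unique(aln$rows), str_chars))
  C <- ncol(mat)
  nr <- nrow(mat)
  col_scores <- matrix(0, 4, C, dimnames = list(RNA_ALPHABET, NULL))
  for (j in seq_len(C)) {
    col <- mat[, j]
    col <- col[col %in% RNA_ALPHABET]
    cnt <- table(factor(col, levels = RNA_ALPHABET))
    f <- (as.numeric(cnt) + 0.5) / (length(col) + 2)
    col_scores[, j] <- log2(f / 0.25)
  }
  pairs <- dotbracket_pairs(aln$consensus)
  bonus <- numeric(nrow(pairs))
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      both <- mat[, i] %in% RNA_ALPHABET & mat[, j] %in% RNA_ALPHABET
      n <- sum(both)
      comp <- sum(can_pair(mat[both, i], mat[both, j]))
      obs <- (comp + 0.5) / (n + 1)
      fi <- (as.numeric(table(factor(mat[both, i], levels = RNA_ALPHABET))) + 0.5) / (n + 2)
      fj <- (as.numeric(table(factor(mat[both, j], levels = RNA_ALPHABET))) + 0.5) / (n + 2)
      p0 <- sum(outer(fi, fj) * PAIRABLE)
      bonus[k] <- log2(obs / p0)
    }
  }
  structure(list(
    columns = C,
    consensus = aln$consensus,
    col_scores = col_scores,
    pair_cols = pairs,
    pair_bonus = bonus,
    train_seqs = vapply(aln$rows, ungap, character(1), USE.NAMES = FALSE),
    calibration = NULL,
    provenance = list(hash = rlang::hash(aln$rows), n_rows = length(aln$rows))
  ), class = "family_model")
}

#' @export
print.family_model <- function(x, ...) {
  cat("<family_model> ", x$columns, " columns, ", nrow(x$pair_cols),
      " consensus pairs, built from ", x$provenance$n_rows, " rows; ",
      if (is.null(x$calibration)) "uncalibrated" else
        sprintf("calibrated (mu=%.2f, beta=%.2f)", x$calibration$mu,
                x$calibration$beta),
      "\n", sep = "")
  invisible(x)
}

## Semi-global placement of the model against a sequence: every model column
## is consumed, the sequence has free flanks.  Returns the raw bit score
## (profile + pair bonuses) and the column -> residue mapping.
model_place <- function(model, seq) {
  chars <- str_chars(seq)
  L <- length(chars)
  C <- model$columns
  ridx <- res_index(chars)
  NEG <- -1e9
  op <- GAP_OPEN_BITS + GAP_EXT_BITS
  ex <- GAP_EXT_BITS
  ## Matrices indexed [i+1, j+1] for i in 0..C, j in 0..L.
  M <- matrix(NEG, C + 1L, L + 1L)
  Ix <- matrix(NEG, C + 1L, L + 1L)  # model column deleted
  Iy <- matrix(NEG, C + 1L, L + 1L)  # sequence residue inserted
  M[1, ] <- 0                        # free leading flank
  for (i in seq_len(C)) {
    si <- ifelse(is.na(ridx), 0, model$col_scores[cbind(ridx, i)])
    prev_best <- pmax(M[i, ], Ix[i, ], Iy[i, ])
    M[i + 1L, 2L:(L + 1L)] <- si + prev_best[1L:L]
    Ix[i + 1L, ] <- pmax(M[i, ] - op, Ix[i, ] - ex)
    ## Iy[i+1, j] = max_{k<j} M[i+1, k] - op - ex*(j-k)
    run <- cummax(M[i + 1L, ] + ex * (0:L))
    Iy[i + 1L, 2L:(L + 1L)] <- run[1L:L] - op - ex * (1L:L)
  }
  ends <- pmax(M[C + 1L, ], Ix[C + 1L, ])
  jend <- which.max(ends) - 1L
  raw <- ends[jend + 1L]

  ## Traceback: recover column -> sequence-position mapping and insert slots.
  ## State semantics at (i, j): "M" = column i aligned to residue j;
  ## "Ix" = column i deleted after consuming j residues; "Iy" = residues up
  ## to j inserted after column i.  Matrix offsets are [i+1, j+1].
  map <- rep(NA_integer_, C)                 # seq position aligned to column i
  inserts <- vector("list", C + 1L)          # residue positions in slot 0..C
  for (g in seq_len(C + 1L)) inserts[[g]] <- integer(0)
  eps <- 1e-7
  i <- C; j <- jend
  state <- if (M[C + 1L, jend + 1L] >= Ix[C + 1L, jend + 1L] - eps) "M" else "Ix"
  if (jend < L) inserts[[C + 1L]] <- (jend + 1L):L
  while (i > 0L) {
    if (state == "M") {
      map[i] <- j
      vM <- M[i, j]; vIx <- Ix[i, j]; vIy <- Iy[i, j]   # predecessors at (i-1, j-1)
      i <- i - 1L; j <- j - 1L
      if (i == 0L) break
      best <- max(vM, vIx, vIy)
      state <- if (vM >= best - eps) "M" else if (vIx >= best - eps) "Ix" else "Iy"
    } else if (state == "Ix") {
      vM <- M[i, j + 1L] - op
      vX <- Ix[i, j + 1L] - ex
      i <- i - 1L
      if (i == 0L) break
      state <- if (vM >= vX - eps) "M" else "Ix"
    } else { # "Iy" at (i, j): residues k+1..j inserted after column i
      target <- Iy[i + 1L, j + 1L]
      k <- j - 1L
      while (k > 0L &&
             abs((M[i + 1L, k + 1L] - op - ex * (j - k)) - target) > eps) {
        k <- k - 1L
      }
      inserts[[i + 1L]] <- c((k + 1L):j, inserts[[i + 1L]])
      j <- k
      state <- "M"
    }
  }
  if (j > 0L) inserts[[1L]] <- c(seq_len(j), inserts[[1L]])

  ## Pair bonuses for consensus pairs whose aligned residues can pair.
  bonus <- 0
  if (nrow(model$pair_cols)) {
    for (k in seq_len(nrow(model$pair_cols))) {
      a <- map[model$pair_cols[k, 1]]
      b <- map[model$pair_cols[k, 2]]
      if (!is.na(a) && !is.na(b) && can_pair(chars[a], chars[b])) {
        bonus <- bonus + model$pair_bonus[k]
      }
    }
  }
  list(score = raw + bonus, map = map, inserts = inserts)
}

#' Score sequences with a family model
#'
#' @param model a `family_model`.
#' @param seqs character vector of sequences.
#' @return numeric vector of raw bit scores.
#' @export
model_score <- function(model, seqs) {
  vapply(seqs, function(s) model_place(model, s)$score, numeric(1),
         USE.NAMES = FALSE)
}

## Dinucleotide Markov sampler estimated from a set of sequences; preserves
## composition of the training material in the null.
null_sampler_markov <- function(train_seqs) {
  concat <- paste(train_seqs, collapse = "")
  ch <- str_chars(concat)
  ch <- ch[ch %in% RNA_ALPHABET]
  p1 <- (as.numeric(table(factor(ch, levels = RNA_ALPHABET))) + 1) / (length(ch) + 4)
  trans <- matrix(1, 4, 4, dimnames = list(RNA_ALPHABET, RNA_ALPHABET))
  if (length(ch) > 1L) {
    for (k in seq_len(length(ch) - 1L)) {
      trans[ch[k], ch[k + 1L]] <- trans[ch[k], ch[k + 1L]] + 1
    }
  }
  trans <- trans / rowSums(trans)
  function(n) {
    out <- character(n)
    out[1] <- sample(RNA_ALPHABET, 1, prob = p1)
    for (k in seq_len(n - 1L)) {
      out[k + 1L] <- sample(RNA_ALPHABET, 1, prob = trans[out[k], ])
    }
    paste(out, collapse = "")
  }
}

#' Calibrate a family model
#'
#' Scores `n_samples` background sequences of consensus length drawn from a
#' dinucleotide Markov null estimated on the member sequences (or a caller
#' provided sampler) and fits a Gumbel location/scale by the method of
#' moments.  Reproducible given `seed`.
#'
#' @param model a built `family_model`.
#' @param n_samples number of null samples (>= 30; default 200).
#' @param seed integer RNG seed.
#' @param null_sampler optional function `(length) -> sequence` used instead
#'   of the dinucleotide null.
#' @return the model with a `calibration` slot (`mu`, `beta`, `n_samples`).
#' @export
model_calibrate <- function(model, n_samples = 200L, seed = 1L,
                            null_sampler = NULL) {
  stopifnot(inherits(model, "family_model"))
  if (n_samples < 30L) stop("calibration error: n_samples must be >= 30")
  sampler <- null_sampler %||% null_sampler_markov(model$train_seqs)
  old <- .Random.seed_exists()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  scores <- vapply(seq_len(n_samples), function(k) {
    model_place(model, sampler(model$columns))$score
  }, numeric(1))
  beta <- sd(scores) * sqrt(6) / pi
  mu <- mean(scores) - EULER_GAMMA * beta
  model$calibration <- list(mu = mu, beta = beta, n_samples = n_samples,
                            seed = as.integer(seed))
  model
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Eulerian-walk shuffle: the returned sequence has exactly the dinucleotide
#' (and hence mononucleotide) counts of the input, with first and last
#' residue fixed.  Used for shuffled controls; sampling is drawn from R's
#' RNG, so results are reproducible under [set.seed()].
#'
#' @param seq residue string (length >= 3 for a non-trivial shuffle).
#' @return shuffled string.
#' @export
dinucleotide_shuffle <- function(seq) {
  ch <- str_chars(seq)
  n <- length(ch)
  if (n < 3L) return(seq)
  ## successor lists of the dinucleotide multigraph
  succ <- split(ch[-1], ch[-n])
  for (attempt in seq_len(10000L)) {
    ## shuffle each successor list, then force an edge to the terminal
    ## residue to be last where present (Eulerian-path validity is checked
    ## by walking; resample on failure -- rare for short RNAs)
    s <- lapply(succ, sample)
    walk <- character(n)
    walk[1] <- ch[1]
    ptr <- lapply(s, function(x) 1L)
    ok <- TRUE
    for (k in 2:n) {
      prev <- walk[k - 1L]
      p <- ptr[[prev]]
      if (is.null(p) || p > length(s[[prev]])) {
        ok <- FALSE
        break
      }
      walk[k] <- s[[prev]][p]
      ptr[[prev]] <- p + 1L
    }
    if (ok) return(paste(walk, collapse = ""))
  }
  stop("dinucleotide shuffle failed to find an Eulerian walk")
}

gumbel_tail <- function(s, mu, beta) {
  ## P(X >= s) under Gumbel(mu, beta); numerically safe for deep tails.
  z <- (s - mu) / beta
  -expm1(-exp(-z))
}

#' Evaluate sequences with a calibrated family model
#'
#' The E-value is the database-size-scaled tail of the calibrated Gumbel
#' null: `E = (database_size / columns) * P(score >= s)`.  Doubling the
#' database size exactly doubles every E-value.
#'
#' @param model a calibrated `family_model`.
#' @param seqs tibble with `id` and `seq` (or character vector).
#' @param database_size database size in nucleotides.
#' @return tibble `id`, `score`, `evalue`, in input order.
#' @export
model_search <- function(model, seqs, database_size) {
  if (is.null(model$calibration)) stop("state error: model is not calibrated")
  if (is.character(seqs)) seqs <- tibble(id = paste0("seq", seq_along(seqs)), seq = seqs)
  if (nrow(seqs) == 0L) {
    return(tibble(id = character(), score = numeric(), evalue = numeric()))
  }
  sc <- model_score(model, seqs$seq)
  ev <- (database_size / model$columns) *
    gumbel_tail(sc, model$calibration$mu, model$calibration$beta)
  tibble(id = seqs$id, score = sc, evalue = ev)
}

#' Align sequences to a family model
#'
#' Each sequence is placed with the same semi-global scorer used for search;
#' rows are merged over the model columns, with inserted residues collected
#' into shared gap columns so that removing gaps from any row reproduces its
#' input sequence.  The model consensus structure is preserved over the
#' model columns (`.` at insert columns).
#'
#' @param model a `family_model`.
#' @param seqs tibble with `id` and `seq` (or character vector).
#' @return an `rna_alignment` with consensus.
#' @export
model_align <- function(model, seqs) {
  if (is.character(seqs)) seqs <- tibble(id = paste0("seq", seq_along(seqs)), seq = seqs)
  if (nrow(seqs) == 0L) stop("model_align error: no sequences")
  C <- model$columns
  placements <- lapply(seqs$seq, function(s) model_place(model, s))
  ins_len <- vapply(0:C, function(g) {
    max(vapply(placements, function(p) length(p$inserts[[g + 1L]]), integer(1)))
  }, integer(1))
  rows <- vapply(seq_len(nrow(seqs)), function(r) {
    p <- placements[[r]]
    ch <- str_chars(seqs$seq[r])
    out <- character(0)
    for (g in 0:C) {
      ins <- p$inserts[[g + 1L]]
      pad <- ins_len[g + 1L] - length(ins)
      out <- c(out, ch[ins], rep("-", pad))
      if (g < C) {
        pos <- p$map[g + 1L]
        out <- c(out, if (is.na(pos)) "-" else ch[pos])
      }
    }
    paste(out, collapse = "")
  }, character(1))
  cons_ch <- character(0)
  db <- str_chars(model$consensus)
  for (g in 0:C) {
    cons_ch <- c(cons_ch, rep(".", ins_len[g + 1L]))
    if (g < C) cons_ch <- c(cons_ch, db[g + 1L])
  }
  rna_alignment(seqs$id, rows, consensus = paste(cons_ch, collapse = ""))
}
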