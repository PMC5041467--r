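simple_alignment <- function(rows, consensus = NULL) {
  rna_alignment(paste0("r", seq_along(rows)), rows, consensus = consensus)
}

test_that("model building needs a consensus and is frequency-determined", {
  aln <- simple_alignment("GGGCGAAAGCGCCC", consensus = "((((......))))")
  m1 <- model_build(aln)
  expect_equal(m1$columns, 14L)
  expect_error(model_build(simple_alignment("ACGU")), "no consensus")

  ## replication of identical rows leaves frequencies (hence scores) unchanged
  aln4 <- simple_alignment(rep("GGGCGAAAGCGCCC", 4), consensus = "((((......))))")
  m4 <- model_build(aln4)
  expect_equal(m1$col_scores, m4$col_scores, tolerance = 1e-12)
  expect_equal(m1$pair_bonus, m4$pair_bonus, tolerance = 1e-12)
})

test_that("the source row is the top-scoring sequence of its own model", {
  aln <- simple_alignment("GGGCGAAAGCGCCC", consensus = "((((......))))")
  m <- model_build(aln)
  own <- model_score(m, "GGGCGAAAGCGCCC")
  set.seed(61)
  others <- vapply(1:25, function(k) model_score(m, random_rna(14)), numeric(1))
  expect_true(all(others < own))
})

test_that("a compensatory pair column earns a positive covariance bonus", {
  ## rows share structure but swap G:C -> C:G at the outermost pair
  aln <- simple_alignment(c("GGGCGAAAGCGCCC", "CGGCGAAAGCGCCG"),
                          consensus = "((((......))))")
  m <- model_build(aln)
  outer_pair <- which(m$pair_cols[, 1] == 1L)
  expect_gt(m$pair_bonus[outer_pair], 0)
  ## hand computation from the 2x2 counts with 0.5 pseudocounts:
  ## obs = (2 + 0.5)/(2 + 1); marginals G/C at 1.5/4 each, others 0.5/4
  fi <- c(A = 0.125, C = 0.375, G = 0.375, U = 0.125)
  fj <- c(A = 0.125, C = 0.375, G = 0.375, U = 0.125)
  p0 <- fi["A"] * fj["U"] + fi["U"] * fj["A"] + fi["G"] * fj["C"] +
    fi["C"] * fj["G"] + fi["G"] * fj["U"] + fi["U"] * fj["G"]
  expect_equal(m$pair_bonus[outer_pair], log2((2.5 / 3) / unname(p0)),
               tolerance = 1e-12)
})

test_that("calibration is seeded, bounded and reproducible", {
  aln <- simple_alignment(c("GGGCGAAAGCGCCC", "GGGCGAAAGCGCCC"),
                          consensus = "((((......))))")
  m <- model_build(aln)
  expect_error(model_calibrate(m, n_samples = 10), "calibration error")
  c1 <- model_calibrate(m, seed = 9)
  c2 <- model_calibrate(m, seed = 9)
  expect_identical(c1$calibration, c2$calibration)
  c3 <- model_calibrate(m, seed = 10)
  expect_false(identical(c1$calibration$mu, c3$calibration$mu))
})

test_that("null sequences are not called significant under their own null", {
  aln <- simple_alignment(c("GGGCGAAAGCGCCC", "GGGCGAAAGCGCCC"),
                          consensus = "((((......))))")
  m <- model_calibrate(model_build(aln), seed = 11)
  sampler <- famforge:::null_sampler_markov(m$train_seqs)
  set.seed(12)
  nulls <- tibble::tibble(id = paste0("n", 1:50),
                          seq = vapply(1:50, function(k) sampler(14L), character(1)))
  ev <- model_search(m, nulls, database_size = 1e6)
  expect_gt(median(ev$evalue), 1)          # null scores stay insignificant
  expect_lt(mean(ev$evalue < 0.001), 0.1)
})

test_that("E-values double with database size and respect calibration state", {
  aln <- simple_alignment(c("GGGCGAAAGCGCCC", "GGGCGAAAGCGCCC"),
                          consensus = "((((......))))")
  m0 <- model_build(aln)
  expect_error(model_search(m0, tibble::tibble(id = "a", seq = "ACGU"), 1e6),
               "not calibrated")
  m <- model_calibrate(m0, seed = 13)
  seqs <- tibble::tibble(id = c("a", "b"),
                         seq = c("GGGCGAAAGCGCCC", random_rna(20)))
  e1 <- model_search(m, seqs, 1e6)
  e2 <- model_search(m, seqs, 2e6)
  expect_equal(e2$evalue, 2 * e1$evalue, tolerance = 1e-12)
  expect_equal(nrow(model_search(m, seqs[0, ], 1e6)), 0L)
})

test_that("members outscore their dinucleotide shuffles under the model", {
  world <- simulate_world(family_sim_spec(seed = 42))
  seqs <- vapply(world$family, function(f) f$seq, character(1))
  input <- tibble::tibble(id = "in", seq = seqs[["8"]])
  aln <- rna_alignment(c("in", "sib"), c(seqs[["8"]], seqs[["9"]]))
  fb <- fold_backend_nussinov()
  aln$consensus <- fb$fold_alignment(aln)$structure
  m <- model_calibrate(model_build(aln), seed = 15)
  true_scores <- model_score(m, unname(seqs))
  set.seed(16)
  shuffled <- unlist(lapply(seqs, function(s) {
    vapply(1:5, function(k) dinucleotide_shuffle(s), character(1))
  }))
  null_scores <- model_score(m, shuffled)
  expect_gt(median(true_scores), quantile(null_scores, 0.95))
})

test_that("model alignment round-trips sequences through gap removal", {
  aln <- simple_alignment(c("GGGCGAAAGCGCCC", "GGGCGAAAGCGCCC"),
                          consensus = "((((......))))")
  m <- model_build(aln)
  expect_error(model_align(m, tibble::tibble(id = character(), seq = character())),
               "no sequences")
  seqs <- tibble::tibble(
    id = c("exact", "del", "ins", "flank"),
    seq = c("GGGCGAAAGCGCCC", "GGCGAAAGCGCC", "GGGCGAAAAAGCGCCC",
            "UUGGGCGAAAGCGCCCAA"))
  out <- model_align(m, seqs)
  expect_equal(length(out$rows), 4L)
  for (i in 1:4) {
    expect_equal(gsub("[-.]", "", out$rows[i]), seqs$seq[i], info = seqs$id[i])
  }
  ## a sequence equal to the single-row consensus aligns gap-free
  solo <- model_align(m, tibble::tibble(id = "x", seq = "GGGCGAAAGCGCCC"))
  expect_false(grepl("-", solo$rows[1]))
  ## consensus is preserved over model columns
  expect_equal(solo$consensus, "((((......))))")
})

test_that("dinucleotide shuffling preserves dinucleotide counts", {
  set.seed(17)
  for (k in 1:20) {
    s <- random_rna(sample(10:80, 1))
    sh <- dinucleotide_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(dinucleotide_counts(sh), dinucleotide_counts(s))
  }
})
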