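test_that("structure projection drops gap columns and unpairs broken pairs", {
  ## gap-free row: projection is the consensus itself
  expect_equal(project_structure("ACGUA", "(...)"), "(...)")
  ## row "A-CGU" under "(())." : pair (2,3) loses an endpoint -> "(.)."
  expect_equal(project_structure("A-CGU", "(())."), "(.).")
  ## row "AC-GU" under "((.))" : dropped column was unpaired -> "(())"
  expect_equal(project_structure("AC-GU", "((.))"), "(())")
  expect_error(project_structure("ACG", "((.))"), "different lengths")
})

test_that("projection preserves balance and non-crossing on random fixtures", {
  set.seed(81)
  for (k in 1:200) {
    n <- sample(6:30, 1)
    db <- random_dotbracket(n)
    row <- paste(sample(c("A", "C", "G", "U", "-"), n, replace = TRUE,
                        prob = c(0.2, 0.2, 0.2, 0.2, 0.2)), collapse = "")
    proj <- project_structure(row, db)
    expect_equal(nchar(proj), sum(strsplit(row, "")[[1]] != "-"))
    pairs <- dotbracket_pairs(proj)   # errors if unbalanced
    if (nrow(pairs) > 1L) {
      for (i in 2:nrow(pairs)) {
        for (j in seq_len(i - 1L)) {
          crossing <- pairs[j, 1] < pairs[i, 1] && pairs[i, 1] < pairs[j, 2] &&
            pairs[j, 2] < pairs[i, 2]
          expect_false(crossing)
        }
      }
    }
  }
})

test_that("base-pair distance counts the pair-set symmetric difference", {
  expect_equal(basepair_distance("((..))", "((..))"), 0L)
  expect_equal(basepair_distance("((..))", "(....)"), 1L)
  expect_equal(basepair_distance("......", "((..))"), 2L)
  expect_error(basepair_distance("....", "((..))"), "different lengths")
})

test_that("base-pair distance behaves as a metric on random structures", {
  set.seed(83)
  for (k in 1:150) {
    n <- sample(4:20, 1)
    a <- random_dotbracket(n)
    b <- random_dotbracket(n)
    c_ <- random_dotbracket(n)
    dab <- basepair_distance(a, b)
    expect_equal(dab, oracle_bp_distance(a, b))
    expect_equal(dab, basepair_distance(b, a))
    expect_identical(basepair_distance(a, a), 0L)
    expect_true(basepair_distance(a, c_) <= dab + basepair_distance(b, c_))
  }
})

test_that("normalized distance projects both consensi onto the shared row", {
  a1 <- rna_alignment(c("in", "x"), c("GGAACC", "GGAACC"), consensus = "((..))")
  a2 <- rna_alignment(c("y", "in"), c("GGAACC", "GGAACC"), consensus = "(....)")
  expect_equal(normalized_structure_distance(a1, a1, "in"), 0)
  expect_equal(normalized_structure_distance(a1, a2, "in"), 1 / 6)
  expect_error(normalized_structure_distance(a1, a2, "zz"), "missing")
  ## unpaired vs full hairpin of length 12: 4 pairs apart, normalized by 12
  h <- rna_alignment(c("in"), "GGGGAAAACCCC", consensus = "((((....))))")
  u <- rna_alignment(c("in"), "GGGGAAAACCCC", consensus = "............")
  expect_equal(normalized_structure_distance(h, u, "in"), 4 / 12)
})

test_that("recovery accounting matches the overlap rule", {
  truth <- tibble::tibble(contig = paste0("c", 1:4), taxid = 1:4,
                          start = c(100L, 200L, 300L, 400L),
                          end = c(170L, 270L, 370L, 470L),
                          strand = "+")
  mk <- function(contig, s, e) tibble::tibble(
    id = paste0(contig, s), contig = contig, start = s, end = e, strand = "+")
  exact <- dplyr::bind_rows(lapply(1:4, function(i) mk(paste0("c", i),
                                                       truth$start[i],
                                                       truth$end[i])))
  r <- recovery_report(exact, truth)
  expect_equal(r$recall, 1.0)
  expect_equal(r$specificity, 1.0)

  with_decoy <- dplyr::bind_rows(exact, mk("c9", 5L, 75L))
  r2 <- recovery_report(with_decoy, truth)
  expect_equal(r2$specificity, 0.8)
  expect_equal(r2$recall, 1.0)

  half <- exact[1:2, ]
  r3 <- recovery_report(half, truth)
  expect_equal(r3$recall, 0.5)
  expect_equal(r3$specificity, 1.0)

  ## 50% reciprocal overlap boundary: a shifted interval of equal length
  ## overlapping by half counts, a quarter overlap does not
  shifted <- mk("c1", 135L, 205L)
  expect_equal(recovery_report(shifted, truth)$recall, 1 / 4)
  far <- mk("c1", 155L, 225L)
  expect_equal(recovery_report(far, truth)$recall, 0)
  expect_error(recovery_report(exact, truth[0, ]), "undefined recall")
})
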