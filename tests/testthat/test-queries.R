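members_tbl <- function(seqs) tibble::tibble(id = paste0("m", seq_along(seqs)),
                                             seq = seqs)

test_that("member deduplication keeps the first of near-identical groups", {
  s <- random_rna(40)
  out <- dedupe_members(members_tbl(c(s, s, s)))
  expect_equal(out$id, "m1")

  set.seed(51)
  distinct <- c(random_rna(40), random_rna(40), random_rna(40))
  out2 <- dedupe_members(members_tbl(distinct))
  expect_equal(nrow(out2), 3L)

  ## idempotent and order-stable
  expect_equal(dedupe_members(out2), out2)
})

test_that("dedupe survivors on a six-sequence fixture match the greedy rule", {
  set.seed(53)
  base <- random_rna(60)
  tweak <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  seqs <- c(base, tweak(base, 1), tweak(base, 20), tweak(base, 2),
            random_rna(60), tweak(base, 25))
  m <- members_tbl(seqs)
  ## expected survivors from the SI matrix and greedy scan
  kept <- 1L
  for (i in 2:6) {
    si <- vapply(kept, function(k) sequence_identity(seqs[i], seqs[k]), numeric(1))
    if (all(si <= 0.95)) kept <- c(kept, i)
  }
  expect_equal(dedupe_members(m)$id, paste0("m", kept))
  expect_true(all(c(1, 3, 5) %in% kept))   # divergent ones always survive
  expect_false(2 %in% kept)                # one-substitution twin collapses
})

test_that("query selection takes the first five in member order", {
  m <- members_tbl(replicate(7, random_rna(30)))
  expect_equal(select_queries(m)$id, paste0("m", 1:5))
  expect_equal(nrow(select_queries(m[1:3, ])), 3L)
  expect_error(select_queries(m[0, ]), "selection error")
})

test_that("UPGMA clustering respects the cluster budget", {
  m <- members_tbl(replicate(3, random_rna(30)))
  p <- upgma_clusters(si_distance_matrix(m), max_clusters = 5)
  expect_length(p, 3L)                    # <= max inputs: singletons

  ## two tight groups, far apart
  dm <- list(labels = paste0("s", 1:6),
             d = matrix(0.9, 6, 6))
  dm$d[1:3, 1:3] <- 0.05
  dm$d[4:6, 4:6] <- 0.05
  diag(dm$d) <- 0
  p5 <- upgma_clusters(dm, max_clusters = 5)
  expect_true(length(p5) <= 5L)
  p2 <- upgma_clusters(dm, max_clusters = 2)
  expect_equal(p2, list(`1` = paste0("s", 1:3), `2` = paste0("s", 4:6)),
               ignore_attr = TRUE)

  zero <- list(labels = paste0("z", 1:6), d = matrix(0, 6, 6))
  expect_length(upgma_clusters(zero, max_clusters = 2), 1L)

  asym <- dm
  asym$d[1, 2] <- 0.5
  expect_error(upgma_clusters(asym, 2), "symmetric")
})

test_that("UPGMA output is a partition with the expected extremes", {
  set.seed(55)
  m <- members_tbl(replicate(8, random_rna(40)))
  dm <- si_distance_matrix(m)
  for (k in c(1L, 3L, 8L)) {
    p <- upgma_clusters(dm, max_clusters = k)
    expect_true(length(p) <= max(k, 1L))
    expect_setequal(unlist(p), m$id)
    expect_equal(anyDuplicated(unlist(p)), 0L)
  }
  expect_length(upgma_clusters(dm, max_clusters = 8), 8L)
  expect_length(upgma_clusters(dm, max_clusters = 1), 1L)
})

test_that("clustered query selection picks each cluster's first member", {
  one <- members_tbl(random_rna(30))
  expect_equal(select_queries_clustered(one), one)

  s <- random_rna(40)
  five_same <- members_tbl(rep(s, 5))
  expect_equal(nrow(select_queries_clustered(five_same)), 1L)

  ## two distant groups interleaved in member order
  set.seed(57)
  a <- random_rna(60)
  b <- random_rna(60)
  near <- function(s) {
    ch <- strsplit(s, "")[[1]]
    p <- sample(60, 2)
    for (q in p) ch[q] <- sample(setdiff(c("A", "C", "G", "U"), ch[q]), 1)
    paste(ch, collapse = "")
  }
  m <- members_tbl(c(a, b, near(a), near(b), near(a), near(b)))
  out <- select_queries_clustered(m, max_queries = 2)
  expect_equal(out$id, c("m1", "m2"))
})
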