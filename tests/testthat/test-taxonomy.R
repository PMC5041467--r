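test_that("taxonomy loading validates structure", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("1\t1\tno rank\troot", tf)
  tr <- load_taxonomy(tf)
  expect_equal(tr$root, 1L)
  expect_equal(nrow(tr$nodes), 1L)

  writeLines(c("1\t1\tno rank\troot", "2\t1\tgenus\tg", "3\t2\tspecies\ts"), tf)
  tr <- load_taxonomy(tf)
  expect_equal(parent_of(tr, 3), 2L)
  expect_equal(parent_of(tr, 2), 1L)

  ## header rows are detected and skipped
  writeLines(c("taxid\tparent\trank\tname", "1\t1\tno rank\troot"), tf)
  expect_equal(load_taxonomy(tf)$root, 1L)
})

test_that("malformed taxonomies are rejected", {
  expect_error(taxonomy_tree(tibble::tibble(
    taxid = 5, parent = 9, rank = "genus", name = "X")), "reference error")
  expect_error(taxonomy_tree(tibble::tibble(
    taxid = c(1, 2), parent = c(1, 2), rank = "r", name = "n")), "root error")
  expect_error(taxonomy_tree(tibble::tibble(
    taxid = c(1, 2, 3), parent = c(1, 3, 2), rank = "r", name = "n")),
    "root error|cycle")
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), tf)
  expect_error(load_taxonomy(tf), "empty")
})

test_that("parent_of is a fixpoint at the root and errors on unknown ids", {
  tr <- toy_taxonomy()
  expect_equal(parent_of(tr, 1), 1L)
  expect_equal(parent_of(tr, 6), 4L)
  expect_error(parent_of(tr, 99), "unknown taxon")
})

test_that("scopes exclude the previous round's sub-tree", {
  tr <- toy_taxonomy()
  ## current Enterobacteriaceae (2), previous Enterobacter (4):
  ## everything in the family except the Enterobacter sub-tree
  sc <- scope_for_iteration(tr, 2, 4)
  expect_setequal(taxa_in_scope(tr, sc), c(2L, 5L, 7L))

  expect_setequal(taxa_in_scope(tr, scope_for_iteration(tr, 2, NULL)),
                  c(2L, 4L, 5L, 6L, 7L))
  expect_equal(taxa_in_scope(tr, scope_for_iteration(tr, 6, NULL)), 6L)
  expect_setequal(taxa_in_scope(tr, scope_for_iteration(tr, 1, NULL)), 1:7)
  expect_setequal(taxa_in_scope(tr, scope_for_iteration(tr, 1, 2)),
                  c(1L, 3L))

  ## previous must be a strict descendant of current
  expect_error(scope_for_iteration(tr, 4, 5), "scope error")
  expect_error(scope_for_iteration(tr, 2, 2), "scope error")
})

test_that("taxa_in_scope matches the brute-force traversal oracle", {
  for (s in 1:20) {
    n <- sample(5:200, 1)
    tbl <- random_tree_table(n, seed = 4000 + s)
    tr <- taxonomy_tree(tbl)
    inc <- sample(tbl$taxid, 1)
    expect_equal(taxa_in_scope(tr, scope_for_iteration(tr, inc, NULL)),
                 oracle_descendants(tbl, inc))
    desc <- setdiff(oracle_descendants(tbl, inc), inc)
    if (length(desc)) {
      exc <- desc[sample.int(length(desc), 1)]
      expect_equal(
        taxa_in_scope(tr, scope_for_iteration(tr, inc, exc)),
        setdiff(oracle_descendants(tbl, inc), oracle_descendants(tbl, exc)))
    }
  }
})

test_that("full ascent scopes partition the taxonomy", {
  for (s in 1:10) {
    n <- sample(8:120, 1)
    tbl <- random_tree_table(n, seed = 5000 + s)
    tr <- taxonomy_tree(tbl)
    start <- sample(tbl$taxid[-1], 1)
    ## round 1: parent of the start node, no exclusion (initial phase)
    cur <- parent_of(tr, start)
    scopes <- list(taxa_in_scope(tr, scope_for_iteration(tr, cur, NULL)))
    while (parent_of(tr, cur) != cur) {
      nxt <- parent_of(tr, cur)
      scopes[[length(scopes) + 1L]] <-
        taxa_in_scope(tr, scope_for_iteration(tr, nxt, cur))
      cur <- nxt
    }
    ## later rounds pairwise disjoint, union covers all taxa
    if (length(scopes) > 1L) {
      for (i in 2:length(scopes)) {
        for (j in seq_len(i - 1L)) {
          if (j == 1L) next  # round 1 overlaps nothing later by construction
          expect_length(intersect(scopes[[i]], scopes[[j]]), 0)
        }
      }
    }
    expect_setequal(sort(unique(unlist(scopes))), tbl$taxid)
  }
})
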